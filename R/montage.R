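#' Read an electrode montage
#'
#' A montage is a CSV table with columns `name, x, y, z`: 10-20-style channel
#' names and scalp coordinates on a unit sphere. Coordinates are carried as
#' metadata; the analysis itself only uses channel names and their order.
#'
#' @param path Path to a montage CSV.
#' @return A `data.frame` of class `montage` with columns `name, x, y, z`.
#' @seealso [default_montage()]
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_invalid("montage file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_montage(df)
}

#' Coerce a data frame to a montage
#'
#' @param df Data frame with at least a `name` column; `x, y, z` optional
#'   (default 0).
#' @return A `montage` data frame.
#' @export
as_montage <- function(df) {
  if (inherits(df, "montage")) return(df)
  if (!is.data.frame(df) || !"name" %in% names(df))
    stop_invalid("a montage needs a 'name' column")
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name))
    stop_invalid("duplicate channel names in montage: %s",
                 paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (cc in c("x", "y", "z")) if (is.null(df[[cc]])) df[[cc]] <- 0
  df <- df[, c("name", "x", "y", "z")]
  class(df) <- c("montage", "data.frame")
  df
}

#' Default 62-channel montage
#'
#' The packaged 62-channel extended 10-20 layout (10-10 names, midline plus
#' lateral rows FP/AF/F/FC/C/CP/P/PO/O and temporal T/FT/TP channels), with
#' schematic unit-sphere coordinates.
#'
#' @return A `montage` data frame with 62 rows.
#' @export
default_montage <- function() {
  read_montage(system.file("extdata", "montage62.csv", package = "plvnet",
                           mustWork = TRUE))
}

# Construct the standard 62-channel layout in code. Used to generate the
# packaged CSV; row geometry is schematic (anterior-posterior row position and
# lateral offset by electrode number), not digitized positions.
standard_montage62 <- function() {
  rows <- list(
    FP = list(y = 0.92, nums = c(1, 2), z_mid = "FPZ"),
    AF = list(y = 0.75, nums = c(3, 4, 7, 8), z_mid = NULL),
    F  = list(y = 0.55, nums = c(1, 2, 3, 4, 5, 6, 7, 8), z_mid = "FZ"),
    FC = list(y = 0.30, nums = c(1, 2, 3, 4, 5, 6), z_mid = "FCZ"),
    FT = list(y = 0.30, nums = c(7, 8), z_mid = NULL),
    C  = list(y = 0.00, nums = c(1, 2, 3, 4, 5, 6), z_mid = "CZ"),
    T  = list(y = 0.00, nums = c(7, 8), z_mid = NULL),
    CP = list(y = -0.30, nums = c(1, 2, 3, 4, 5, 6), z_mid = "CPZ"),
    TP = list(y = -0.30, nums = c(7, 8), z_mid = NULL),
    P  = list(y = -0.55, nums = c(1, 2, 3, 4, 5, 6, 7, 8), z_mid = "PZ"),
    PO = list(y = -0.75, nums = c(3, 4, 5, 6, 7, 8), z_mid = "POZ"),
    O  = list(y = -0.92, nums = c(1, 2), z_mid = "OZ")
  )
  out <- list()
  for (pre in names(rows)) {
    r <- rows[[pre]]
    if (!is.null(r$z_mid))
      out[[length(out) + 1L]] <- data.frame(name = r$z_mid, x = 0, y = r$y)
    for (k in r$nums) {
      side <- if (k %% 2 == 1) -1 else 1          # odd = left, even = right
      lat <- 0.12 + 0.105 * ((k + 1) %/% 2 - 1)   # 1,2 innermost ... 7,8 outer
      out[[length(out) + 1L]] <- data.frame(
        name = paste0(pre, k), x = side * lat, y = r$y)
    }
  }
  df <- do.call(rbind, out)
  df$z <- sqrt(pmax(0, 1 - df$x^2 - df$y^2))
  as_montage(df)
}

# Split a 10-20 channel name into (prefix, suffix). Suffix "Z" marks midline.
parse_channel <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9]+|[Zz])$", name))[[1]]
  if (length(m) != 3L) return(NULL)
  list(prefix = toupper(m[2]), suffix = toupper(m[3]))
}

#' Build the 10-region scalp atlas from a montage
#'
#' Channels are assigned to a hemisphere by numeric suffix (odd = left,
#' even = right; midline `Z` channels are excluded) and to a lobe by their
#' letter prefix: FP/AF/F frontal, FC/C/CP central, FT/T/TP temporal,
#' P parietal, PO/O occipital. This yields the 10 non-overlapping regions
#' LF, RF, LC, RC, LT, RT, LP, RP, LO, RO.
#'
#' @param montage A `montage` data frame.
#' @return A `data.frame` of class `region_atlas` with columns
#'   `channel, region`.
#' @export
build_region_atlas <- function(montage) {
  montage <- as_montage(montage)
  lobe_of <- c(FP = "F", AF = "F", F = "F",
               FC = "C", C = "C", CP = "C",
               FT = "T", T = "T", TP = "T",
               P = "P",
               PO = "O", O = "O")
  rows <- list()
  for (ch in montage$name) {
    p <- parse_channel(ch)
    if (is.null(p) || p$suffix == "Z") next        # midline / unparseable: skip
    if (!p$prefix %in% names(lobe_of)) next
    hemi <- if (as.integer(p$suffix) %% 2 == 1) "L" else "R"
    rows[[length(rows) + 1L]] <- data.frame(
      channel = ch, region = paste0(hemi, lobe_of[[p$prefix]]))
  }
  df <- do.call(rbind, rows)
  as_region_atlas(df, montage)
}

#' Coerce a channel-region table to a region atlas
#'
#' @param df Data frame with columns `channel, region`.
#' @param montage Optional montage; if given, every atlas channel must be in it.
#' @return A `region_atlas` data frame.
#' @export
as_region_atlas <- function(df, montage = NULL) {
  if (!is.data.frame(df) || !all(c("channel", "region") %in% names(df)))
    stop_invalid("an atlas needs 'channel' and 'region' columns")
  df$channel <- as.character(df$channel)
  df$region <- as.character(df$region)
  if (anyDuplicated(df$channel))
    stop_invalid("atlas assigns a channel to more than one region")
  bad <- setdiff(unique(df$region), REGION_ORDER)
  if (length(bad))
    stop_invalid("unknown atlas regions: %s", paste(bad, collapse = ", "))
  if (!is.null(montage)) {
    montage <- as_montage(montage)
    missing <- setdiff(df$channel, montage$name)
    if (length(missing))
      stop_invalid("atlas channels not in montage: %s",
                   paste(missing, collapse = ", "))
  }
  df <- df[, c("channel", "region")]
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' Read a region atlas CSV
#'
#' @param path CSV with columns `channel, region`.
#' @param montage Optional montage to validate against.
#' @return A `region_atlas` data frame.
#' @export
read_atlas <- function(path, montage = NULL) {
  if (!file.exists(path)) stop_invalid("atlas file not found: %s", path)
  as_region_atlas(utils::read.csv(path, stringsAsFactors = FALSE), montage)
}

#' Default 10-region atlas for the packaged 62-channel montage
#'
#' @return A `region_atlas` data frame (54 lateral channels; the 8 midline
#'   channels are not part of any region).
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas10.csv", package = "plvnet",
                         mustWork = TRUE))
}
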