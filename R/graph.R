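#' Small-world graph metrics of a PLV network
#'
#' Computes the standard weighted small-world properties of a connectivity
#' matrix. In `weighted` mode, off-diagonal weights are normalized by their
#' maximum; the per-node clustering coefficient uses Onnela's geometric-mean
#' triangle form; shortest-path distances use `1/weight`; the characteristic
#' path length (CPL) is the mean finite pairwise distance; global efficiency
#' (Ge) is the mean inverse distance over pairs; local efficiency (Le) is the
#' global efficiency of each node's neighborhood subgraph; node degree (ND)
#' is the node strength (sum of incident normalized weights). In
#' `proportional_threshold` mode the strongest `density` fraction of edges is
#' kept, the graph binarized, and the binary formulas used.
#'
#' @param M A [plv_matrix()] or a symmetric numeric matrix with entries in
#'   \[0, 1\].
#' @param mode `"weighted"` (default) or `"proportional_threshold"`.
#' @param density Fraction of strongest edges kept in threshold mode,
#'   in (0, 1).
#' @return An object of class `graph_metrics`: per-node `cc`, `le`, `nd`;
#'   global `cpl`, `ge`; `connected` flag (CPL is over finite pairs only and
#'   flagged when the graph is disconnected).
#' @export
compute_metrics <- function(M, mode = c("weighted", "proportional_threshold"),
                            density = 0.2) {
  mode <- match.arg(mode)
  band <- stage <- subject_id <- NA
  if (inherits(M, "plv_matrix")) {
    band <- M$band; stage <- M$stage; subject_id <- M$subject_id
    W <- M$values
  } else {
    W <- as.matrix(M)
  }
  n <- nrow(W)
  if (n != ncol(W)) stop_invalid("matrix must be square")
  if (max(abs(W - t(W))) > 1e-9) stop_invalid("matrix must be symmetric")
  if (any(W < 0 | W > 1)) stop_invalid("weights must be in [0, 1]")
  channels <- rownames(W)
  if (is.null(channels)) channels <- paste0("n", seq_len(n))
  diag(W) <- 0

  if (mode == "proportional_threshold") {
    if (!is.finite(density) || density <= 0 || density >= 1)
      stop_invalid("density must be in (0, 1)")
    ut <- which(upper.tri(W))
    keep <- ut[order(W[ut], decreasing = TRUE)[seq_len(round(density * length(ut)))]]
    B <- matrix(0, n, n)
    B[keep] <- 1
    W <- B + t(B)
  } else {
    mx <- max(W)
    if (mx > 0) W <- W / mx
  }

  k <- rowSums(W > 0)
  W3 <- W^(1 / 3)
  cc_num <- diag(W3 %*% W3 %*% W3)
  cc <- ifelse(k >= 2, cc_num / (k * (k - 1)), 0)
  nd <- rowSums(W)

  D <- dist_matrix(W)
  off <- D[upper.tri(D)]
  finite <- is.finite(off)
  connected <- all(finite)
  cpl <- if (any(finite)) mean(off[finite]) else Inf
  ge <- mean(ifelse(finite, 1 / off, 0))

  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) { le[i] <- 0; next }
    Dn <- dist_matrix(W[nb, nb, drop = FALSE])
    offn <- Dn[upper.tri(Dn)]
    le[i] <- mean(ifelse(is.finite(offn), 1 / offn, 0))
  }

  names(cc) <- names(le) <- names(nd) <- channels
  structure(list(cc = cc, le = le, nd = nd, cpl = cpl, ge = ge,
                 connected = connected, mode = mode,
                 density = if (mode == "proportional_threshold") density else NA,
                 band = band, stage = stage, subject_id = subject_id),
            class = "graph_metrics")
}

# All-pairs shortest-path distances with edge lengths 1/weight
# (1 for binary graphs); Inf for disconnected pairs, 0 diagonal.
dist_matrix <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    D <- matrix(Inf, n, n); diag(D) <- 0
    return(D)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(idx))
  igraph::distances(g, weights = 1 / W[idx])
}

#' @export
print.graph_metrics <- function(x, ...) {
  bn <- if (identical(x$band, "broadband") || is.na(x$band[1])) x$band else x$band$name
  cat(sprintf("<graph_metrics> %s %s @ %s (%s): CPL %.3f, Ge %.3f, mean CC %.3f%s\n",
              x$subject_id, if (is.list(bn)) "?" else bn, x$stage, x$mode,
              x$cpl, x$ge, mean(x$cc),
              if (!x$connected) " [disconnected]" else ""))
  invisible(x)
}

#' Average a per-node metric over scalp regions
#'
#' @param metric Named numeric vector (names = channels), e.g. `$cc` from
#'   [compute_metrics()].
#' @param atlas A `region_atlas` ([default_atlas()], [build_region_atlas()]).
#' @return Named numeric vector of region means in the fixed order
#'   LF, RF, LC, RC, LT, RT, LP, RP, LO, RO.
#' @export
region_average <- function(metric, atlas) {
  if (is.null(names(metric))) stop_invalid("metric must be named by channel")
  atlas <- as_region_atlas(atlas)
  missing <- setdiff(atlas$channel, names(metric))
  if (length(missing))
    stop_invalid("atlas channel(s) missing from metric: %s",
                 paste(missing, collapse = ", "))
  out <- vapply(REGION_ORDER, function(r) {
    ch <- atlas$channel[atlas$region == r]
    if (!length(ch)) return(NA_real_)
    mean(metric[ch])
  }, 0)
  names(out) <- REGION_ORDER
  out
}
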