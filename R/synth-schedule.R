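#' Build a randomized trial schedule
#'
#' The formal docking experiment crosses obstacle types with initial viewing
#' perspectives; the canonical design is 2 obstacle types x 8 perspectives
#' (30 to 240 degrees in 30-degree steps) = 16 trials, presented in random
#' order.
#'
#' @param n_obstacle_types Number of obstacle types (>= 1; canonical 2:
#'   vertical bar and circular frame).
#' @param n_perspectives Number of initial perspectives (>= 1; canonical 8).
#' @param seed Integer seed for the presentation order.
#' @return Data frame with columns `trial, obstacle, angle_deg`: one row per
#'   trial in presentation order, covering every (obstacle, angle) pair once.
#' @examples
#' make_trial_schedule(2, 8, seed = 1)  # 16 trials
#' @export
make_trial_schedule <- function(n_obstacle_types = 2, n_perspectives = 8,
                                seed = 1) {
  n_obstacle_types <- as.integer(n_obstacle_types)
  n_perspectives <- as.integer(n_perspectives)
  if (is.na(n_obstacle_types) || n_obstacle_types < 1)
    stop_invalid("n_obstacle_types must be >= 1")
  if (is.na(n_perspectives) || n_perspectives < 1)
    stop_invalid("n_perspectives must be >= 1")
  obstacles <- if (n_obstacle_types == 2) c("bar", "frame") else
    paste0("type", seq_len(n_obstacle_types))
  angles <- seq(30, by = 30, length.out = n_perspectives)
  grid <- expand.grid(obstacle = obstacles, angle_deg = angles,
                      stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  data.frame(trial = seq_len(nrow(grid)), obstacle = grid$obstacle,
             angle_deg = grid$angle_deg, row.names = NULL)
}
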