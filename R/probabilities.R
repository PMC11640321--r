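#' Probability that a lone agent joins a candidate cluster
#'
#' The join rule that drives huddle formation. A lone macaque that senses a
#' candidate cluster of size \code{n_ci} joins it with probability
#' \deqn{P_{join} = \frac{n_{ci}}{n_{cmax}} \times \frac{1}{T} \times \frac{1}{J}}
#' so larger clusters are more attractive, while warmer temperatures and a
#' higher (more selective) joining threshold both suppress joining. A lone
#' partner counts as a candidate of size 1, which is how new clusters
#' nucleate.
#'
#' @param n_ci Integer size of the candidate cluster (1 for a lone partner).
#' @param n_cmax Integer group size (the maximum attainable cluster size).
#' @param temperature Temperature on the model's 1--10 scale.
#' @param join_threshold Joining threshold J (>= 1); higher values make
#'   agents more selective.
#' @return A probability in \code{[0, 1]}. Vectorised over `n_ci`.
#' @seealso [p_leave()]
#' @examples
#' p_join(35, 70, temperature = 5, join_threshold = 2) # 0.05
#' @export
p_join <- function(n_ci, n_cmax, temperature, join_threshold) {
  stopifnot(
    is.numeric(n_ci), is.numeric(n_cmax),
    is.numeric(temperature), is.numeric(join_threshold),
    length(n_cmax) == 1L, length(temperature) == 1L,
    length(join_threshold) == 1L
  )
  if (temperature < 1) {
    abort("`temperature` must be >= 1 (the join rule divides by T).")
  }
  if (join_threshold < 1) {
    abort("`join_threshold` must be >= 1 (the join rule divides by J).")
  }
  if (any(n_ci < 1) || any(n_ci > n_cmax)) {
    abort("`n_ci` must satisfy 1 <= n_ci <= n_cmax.")
  }
  (n_ci / n_cmax) * (1 / temperature) * (1 / join_threshold)
}

#' Probability that a huddled agent leaves its cluster
#'
#' The leave rule. A clustered macaque leaves with probability
#' \deqn{P_{leave} = \frac{n_{cmax} - n_{ci}}{n_{cmax}} \times \frac{1}{L}}
#' which vanishes when the whole group shares one cluster (making the full
#' huddle absorbing) and is bounded by \code{1/L}. The leaving threshold L
#' starts at 10, so the per-tick leave probability never exceeds 0.1.
#'
#' @param n_ci Integer size of the agent's current cluster (including the
#'   agent itself).
#' @param n_cmax Integer group size.
#' @param leave_threshold Leaving threshold L (>= 10); higher values make
#'   agents more committed to staying.
#' @return A probability in \code{[0, 0.1]}. Vectorised over `n_ci`.
#' @seealso [p_join()]
#' @examples
#' p_leave(10, 70, leave_threshold = 10) # (60/70) * 0.1
#' p_leave(70, 70, leave_threshold = 10) # 0: full huddle is absorbing
#' @export
p_leave <- function(n_ci, n_cmax, leave_threshold) {
  stopifnot(
    is.numeric(n_ci), is.numeric(n_cmax), is.numeric(leave_threshold),
    length(n_cmax) == 1L, length(leave_threshold) == 1L
  )
  if (leave_threshold < 10) {
    abort("`leave_threshold` must be >= 10.")
  }
  if (any(n_ci < 1) || any(n_ci > n_cmax)) {
    abort("`n_ci` must satisfy 1 <= n_ci <= n_cmax.")
  }
  ((n_cmax - n_ci) / n_cmax) * (1 / leave_threshold)
}
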