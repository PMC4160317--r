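# Constant-velocity Kalman filtering of head-center motion.
#
# State x = (x, y, vx, vy); observation z = (zx, zy). F advances position by
# velocity * dt; H observes position. Q = q * diag(1/4, 1/4, 1, 1), R = r * I,
# standard near-constant-velocity defaults at video frame rates.

kalmanF <- function(dt) {
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           dt, 0, 1, 0,
           0, dt, 0, 1), 4, 4)
}

kalmanH <- function() cbind(diag(2), matrix(0, 2, 2))

kalmanQ <- function(q) q * diag(c(0.25, 0.25, 1, 1))

#' Create a Kalman state
#'
#' @param x,y position (px); @param vx,vy velocity (px/frame).
#' @param params a [TrackingParams-class]; sets P0.
#' @return a list with `m` (state mean), `P` (4x4 covariance) and
#'   `effective` (whether the state was observation-associated).
#' @export
kalmanInit <- function(x, y, vx = 0, vy = 0, params = trackingParams()) {
  list(m = c(x, y, vx, vy), P = params@p0 * diag(4), effective = TRUE)
}

#' Kalman prediction (time update)
#'
#' Advances the position by velocity times `dt` under the constant-velocity
#' model and propagates the covariance, `P <- F P F' + Q`.
#'
#' @param state a state from [kalmanInit()] or [kalmanUpdate()].
#' @param params a [TrackingParams-class].
#' @return the prior state at the next frame.
#' @export
kalmanPredict <- function(state, params = trackingParams()) {
  F <- kalmanF(params@dt)
  list(m = drop(F %*% state$m),
       P = F %*% state$P %*% t(F) + kalmanQ(params@q),
       effective = FALSE)
}

#' Kalman measurement update
#'
#' Standard gain `K = P H' (H P H' + R)^{-1}`; in the `r -> 0` limit the
#' posterior position equals the observation, in the `r -> Inf` limit the
#' prior is kept.
#'
#' @param prior state from [kalmanPredict()].
#' @param z observed position `c(zx, zy)`.
#' @param params a [TrackingParams-class].
#' @return the posterior state (marked effective).
#' @export
kalmanUpdate <- function(prior, z, params = trackingParams()) {
  H <- kalmanH()
  S <- H %*% prior$P %*% t(H) + params@r * diag(2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular innovation covariance in Kalman update"))
  K <- prior$P %*% t(H) %*% Sinv
  m <- prior$m + drop(K %*% (z - drop(H %*% prior$m)))
  P <- (diag(4) - K %*% H) %*% prior$P
  P <- (P + t(P)) / 2
  list(m = m, P = P, effective = TRUE)
}
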