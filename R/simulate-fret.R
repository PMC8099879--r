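#' Specification of a two-state smFRET simulation
#'
#' Describes a fold/unfold two-state continuous-time Markov chain observed
#' through donor/acceptor photon counts. The hidden state switches
#' folded -> unfolded at `k_unfold` (s^-1) and back at `k_fold` (s^-1); the
#' folded state has the high FRET efficiency `e_folded`, the unfolded state
#' the low `e_unfolded`. Acceptor mean intensity is `E * total_intensity`,
#' donor mean `(1 - E) * total_intensity`, each with independent Gaussian
#' noise of sd `noise_sigma` (photons/frame).
#'
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory (default 800).
#' @param frame_time exposure per frame in seconds (default 0.03).
#' @param k_unfold,k_fold transition rates (s^-1, >= 0).
#' @param e_folded,e_unfolded FRET efficiencies in (0, 1), folded > unfolded.
#' @param total_intensity mean total photons per frame.
#' @param noise_sigma per-channel Gaussian noise sd (photons/frame).
#' @param seed integer seed.
#' @return A `fret_sim_spec` list.
#' @export
fret_sim_spec <- function(n_traj = 100, n_frames = 800, frame_time = 0.03,
                          k_unfold = 1, k_fold = 1,
                          e_folded = 0.7, e_unfolded = 0.25,
                          total_intensity = 1000, noise_sigma = 70,
                          seed = NULL) {
  stop_if_not_number(k_unfold, "k_unfold", nonneg = TRUE)
  stop_if_not_number(k_fold, "k_fold", nonneg = TRUE)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (e_folded <= 0 || e_folded >= 1 || e_unfolded <= 0 || e_unfolded >= 1)
    stop("FRET efficiencies must lie in (0, 1)")
  if (e_folded <= e_unfolded) stop("e_folded must exceed e_unfolded")
  stop_if_not_number(frame_time, "frame_time", positive = TRUE)
  structure(list(n_traj = as.integer(n_traj), n_frames = as.integer(n_frames),
                 frame_time = frame_time, k_unfold = k_unfold, k_fold = k_fold,
                 e_folded = e_folded, e_unfolded = e_unfolded,
                 total_intensity = total_intensity, noise_sigma = noise_sigma,
                 seed = seed),
            class = "fret_sim_spec")
}

# One-step transition matrix of the sampled two-state chain.
# States: 1 = folded, 2 = unfolded.
fret_transition_matrix <- function(ku, kf, dt) {
  s <- ku + kf
  if (s == 0) return(diag(2))
  e <- exp(-s * dt)
  rbind(c((kf + ku * e) / s, (ku - ku * e) / s),
        c((kf - kf * e) / s, (ku + kf * e) / s))
}

#' Simulate two-state smFRET trajectories
#'
#' Hidden fold/unfold states follow the continuous-time Markov chain of the
#' spec sampled at the frame time (initial state drawn from the stationary
#' distribution); donor and acceptor intensities are Gaussian around the
#' state-dependent means.
#'
#' @param spec a [fret_sim_spec()].
#' @return A list with `trajectories` (list of data frames: `frame`, `donor`,
#'   `acceptor`), `states` (list of integer vectors, 1 = folded,
#'   2 = unfolded), and `spec`.
#' @export
simulate_fret_trajectories <- function(spec) {
  stopifnot(inherits(spec, "fret_sim_spec"))
  with_seed(spec$seed, {
    P <- fret_transition_matrix(spec$k_unfold, spec$k_fold, spec$frame_time)
    p_unf <- if (spec$k_unfold + spec$k_fold > 0)
      spec$k_unfold / (spec$k_unfold + spec$k_fold) else 0.5
    eff <- c(spec$e_folded, spec$e_unfolded)
    trajs <- states <- vector("list", spec$n_traj)
    for (i in seq_len(spec$n_traj)) {
      s <- integer(spec$n_frames)
      s[1] <- 1L + stats::rbinom(1L, 1L, p_unf)
      u <- stats::runif(spec$n_frames - 1L)
      for (t in 2:spec$n_frames)
        s[t] <- if (u[t - 1L] < P[s[t - 1L], 1L]) 1L else 2L
      e <- eff[s]
      acc <- e * spec$total_intensity +
        stats::rnorm(spec$n_frames, 0, spec$noise_sigma)
      don <- (1 - e) * spec$total_intensity +
        stats::rnorm(spec$n_frames, 0, spec$noise_sigma)
      trajs[[i]] <- data.frame(frame = seq_len(spec$n_frames) - 1L,
                               donor = don, acceptor = acc)
      states[[i]] <- s
    }
    list(trajectories = trajs, states = states, spec = spec)
  })
}
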