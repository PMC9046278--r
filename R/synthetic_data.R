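#' Path (chain) graph over p features
#'
#' Unit-weight edges between consecutive features; the simplest structure
#' under which a contiguous support is "graph-smooth".
#'
#' @param p Number of features.
#' @param feature_labels Optional node names.
#' @return A `feature_graph`.
#' @export
chain_graph <- function(p, feature_labels = NULL) {
  A <- matrix(0, p, p)
  if (p > 1) {
    idx <- cbind(seq_len(p - 1), 2:p)
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  feature_graph(A, feature_labels)
}

# Sparse loading with a contiguous support, smoothed along the graph within
# the support by one step of graph diffusion u <- (I + L_S)^{-1} u, then
# unit-normalized.  Zeros outside the support stay exactly zero.
draw_loading <- function(p, sparsity, graph, support = NULL) {
  if (sparsity > p) stop("sparsity cannot exceed feature count", call. = FALSE)
  if (is.null(support)) {
    start <- sample.int(p - sparsity + 1, 1)
    support <- seq(start, length.out = sparsity)
  }
  u <- numeric(p)
  u[support] <- stats::rnorm(sparsity)
  if (!is.null(graph) && sparsity > 1) {
    Ls <- graph$laplacian[support, support, drop = FALSE]
    u[support] <- solve(diag(sparsity) + Ls, u[support])
  }
  # avoid degenerate near-zero draws
  if (sqrt(sum(u^2)) < 1e-8) u[support] <- 1
  u / sqrt(sum(u^2))
}

#' Generate multiset data with known sparse graph-smooth loadings
#'
#' Each dataset is \eqn{X_k = \sum_n z^{[n]} (w_k^{[n]})^T + noise}: shared
#' orthogonal latent time courses drive every set through sparse loadings
#' smoothed along a feature graph, plus Gaussian noise scaled so the
#' per-set entrywise signal-to-noise variance ratio equals `snr`.  The
#' ground truth (latents, loadings, supports, graphs, noise SDs) is
#' returned so solver recovery can be scored exactly.
#'
#' @param n_samples Number of rows shared by all sets.
#' @param feature_counts Integer vector, one feature count per set.
#' @param n_latents Number of shared latent components.
#' @param sparsity Support size per loading (scalar or per set).
#' @param snr Signal-to-noise variance ratio per set (> 0).
#' @param graphs Optional list of `feature_graph`s used for smoothing;
#'   default chain graphs.
#' @param disjoint_supports If `TRUE` (default) different latents load on
#'   disjoint contiguous feature blocks within each set.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `datasets` (list of `feature_matrix`) and `truth`
#'   (class `ground_truth`: `latents`, `loadings[[set]][[latent]]`,
#'   `supports`, `graphs`, `noise_sd`, `seed`).
#' @export
gen_multiset <- function(n_samples, feature_counts, n_latents = 1L,
                         sparsity = 4L, snr = 1, graphs = NULL,
                         disjoint_supports = TRUE, seed = 1L) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (n_latents > n_samples) {
    stop("n_latents cannot exceed n_samples", call. = FALSE)
  }
  M <- length(feature_counts)
  sparsity <- rep_len(as.integer(sparsity), M)
  if (any(sparsity > feature_counts)) {
    stop("sparsity cannot exceed the feature count", call. = FALSE)
  }
  if (is.null(graphs)) graphs <- lapply(feature_counts, chain_graph)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * n_latents), n_samples, n_latents)
    Z <- qr.Q(qr(Z)) * sqrt(n_samples)   # orthogonal, unit-variance columns
    datasets <- vector("list", M)
    loadings <- supports <- vector("list", M)
    noise_sd <- numeric(M)
    for (k in seq_len(M)) {
      p <- feature_counts[k]
      ws <- vector("list", n_latents)
      sps <- vector("list", n_latents)
      if (disjoint_supports && n_latents * sparsity[k] > p) {
        stop("disjoint supports need n_latents * sparsity <= feature count",
             call. = FALSE)
      }
      used <- integer(0)
      for (nl in seq_len(n_latents)) {
        if (disjoint_supports) {
          # contiguous blocks spread across the feature axis
          avail <- setdiff(seq_len(p - sparsity[k] + 1),
                           unlist(lapply(used, function(s) {
                             seq(max(1, s - sparsity[k] + 1), s + sparsity[k] - 1)
                           })))
          start <- if (length(avail) > 0) avail[sample.int(length(avail), 1)]
                   else sample.int(p - sparsity[k] + 1, 1)
          sp <- seq(start, length.out = sparsity[k])
          used <- c(used, sp)
        } else {
          sp <- NULL
        }
        w <- draw_loading(p, sparsity[k], graphs[[k]], support = sp)
        ws[[nl]] <- w
        sps[[nl]] <- which(w != 0)
      }
      sig <- matrix(0, n_samples, p)
      for (nl in seq_len(n_latents)) sig <- sig + Z[, nl] %o% ws[[nl]]
      noise_sd[k] <- sqrt(stats::var(as.numeric(sig)) / snr)
      X <- sig + matrix(stats::rnorm(n_samples * p, sd = noise_sd[k]),
                        n_samples, p)
      labels <- paste0("F", k, "_", seq_len(p))
      for (nl in seq_len(n_latents)) names(ws[[nl]]) <- labels
      datasets[[k]] <- feature_matrix(X, labels, set_id = paste0("set", k))
      loadings[[k]] <- ws
      supports[[k]] <- sps
    }
    truth <- structure(
      list(latents = Z, loadings = loadings, supports = supports,
           graphs = graphs, noise_sd = noise_sd, snr = snr, seed = seed),
      class = "ground_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate paired EEG-like and fNIRS-like recordings
#'
#' EEG channels carry a 10 Hz oscillation whose amplitude drops by
#' `mu_erd_depth` during each action window (event-related
#' desynchronization) on top of broadband noise; the desynchronization
#' begins `erd_lead` seconds before the action marker, reflecting the
#' well-documented pre-movement onset of mu suppression during motor
#' preparation.  fNIRS channels carry the event train convolved with the
#' HRF (the HbO increase) plus a realistic post-preprocessing noise mix:
#' moderate low-frequency drift, a cardiac oscillation with per-channel
#' phase, and white measurement noise.  Marker files for both modalities
#' share the action-start convention (event at time 0).  Setting
#' `event_effect = FALSE` keeps the identical noise structure and markers
#' but removes all event-locked modulation — the matched null recording.
#'
#' @param n_trials Number of events.
#' @param inter_trial Event spacing in seconds (windows must not overlap).
#' @param event_duration Action-window length in seconds.
#' @param mu_erd_depth Fractional mu-amplitude drop during events, in
#'   `(0, 1]`.
#' @param erd_lead Seconds by which mu suppression precedes the marker.
#' @param eeg_rate,fnirs_rate Sampling rates in Hz.
#' @param n_eeg_channels,n_fnirs_channels Channel counts.
#' @param hrf An [gamma_hrf()] kernel at `fnirs_rate`; `NULL` uses the
#'   default.
#' @param noise_sd Length-2 vector: EEG broadband noise SD and fNIRS white
#'   measurement-noise SD (drift and cardiac amplitudes scale with the
#'   latter).
#' @param event_effect If `FALSE`, generate the event-free control.
#' @param seed Integer seed.
#' @return List with `eeg`, `eeg_markers`, `fnirs`, `fnirs_markers`,
#'   `roi_map` (two channels per ROI), and the event times.
#' @export
gen_modalities <- function(n_trials = 8L, inter_trial = 30,
                           event_duration = 3, mu_erd_depth = 0.8,
                           erd_lead = 1.5, eeg_rate = 250, fnirs_rate = 10,
                           n_eeg_channels = 2L, n_fnirs_channels = 4L,
                           hrf = NULL, noise_sd = c(0.5, 0.03),
                           event_effect = TRUE, seed = 1L) {
  if (mu_erd_depth <= 0 || mu_erd_depth > 1) {
    stop("mu_erd_depth must lie in (0, 1]", call. = FALSE)
  }
  if (event_duration >= inter_trial) {
    stop("event windows overlap: event_duration must be < inter_trial",
         call. = FALSE)
  }
  if (is.null(hrf)) hrf <- gamma_hrf(rate = fnirs_rate)
  pre <- 10                      # lead-in before the first event (s)
  total <- pre + n_trials * inter_trial + 10
  events <- pre + (seq_len(n_trials) - 1) * inter_trial
  with_seed(seed, {
    t_eeg <- seq(0, total - 1 / eeg_rate, by = 1 / eeg_rate)
    amp <- rep(1, length(t_eeg))
    if (event_effect) {
      for (ev in events) {
        amp[t_eeg >= ev - erd_lead & t_eeg < ev + event_duration] <-
          1 - mu_erd_depth
      }
    }
    eeg_vals <- vapply(seq_len(n_eeg_channels), function(ch) {
      phase <- stats::runif(1, 0, 2 * pi)
      amp * sin(2 * pi * 10 * t_eeg + phase) +
        stats::rnorm(length(t_eeg), sd = noise_sd[1])
    }, numeric(length(t_eeg)))
    eeg <- timeseries(t_eeg, eeg_vals,
                      paste0("E", seq_len(n_eeg_channels)))

    t_fn <- seq(0, total - 1 / fnirs_rate, by = 1 / fnirs_rate)
    box <- numeric(length(t_fn))
    if (event_effect) {
      for (ev in events) {
        box[t_fn >= ev & t_fn < ev + event_duration] <- 1
      }
    }
    k <- hrf$kernel / fnirs_rate
    resp <- fast_causal_conv(box, k)
    fn_vals <- vapply(seq_len(n_fnirs_channels), function(ch) {
      gain <- stats::runif(1, 0.8, 1.2)
      # moderate drift (tau ~ 0.5 s at 10 Hz), cardiac ~1.1 Hz with a
      # channel-specific phase, plus white measurement noise
      drift <- as.numeric(stats::filter(
        stats::rnorm(length(t_fn), sd = noise_sd[2]), 0.8,
        method = "recursive"))
      cardiac <- 1.5 * noise_sd[2] *
        sin(2 * pi * 1.1 * t_fn + stats::runif(1, 0, 2 * pi))
      white <- stats::rnorm(length(t_fn), sd = noise_sd[2])
      gain * resp + drift + cardiac + white
    }, numeric(length(t_fn)))
    fnirs <- timeseries(t_fn, fn_vals,
                        paste0("N", seq_len(n_fnirs_channels)))
    roi <- paste0("ROI", rep(seq_len(max(1, ceiling(n_fnirs_channels / 2))),
                             each = 2, length.out = n_fnirs_channels))
    list(eeg = eeg,
         eeg_markers = data.frame(time = events, label = "SA"),
         fnirs = fnirs,
         fnirs_markers = data.frame(time = events, label = "SA"),
         roi_map = data.frame(channel = fnirs$channel_labels, roi = roi),
         events = events)
  })
}
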