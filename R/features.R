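#' Feature-extraction configuration
#'
#' Collects the tunable parameters of the three per-window feature families.
#'
#' @param zc_ssc_deadzone amplitude dead zone for the zero-crossing and
#'   slope-sign-change counts (same units as the signal). Default 0.
#' @param wavelet_levels wavelet decomposition depth; 5 gives 32 terminal
#'   packet nodes per channel.
#' @param wavelet_variant `"packet"` (energies of the 2^levels terminal
#'   wavelet-packet nodes, the default), `"all_nodes"` (every node of the
#'   tree) or `"dwt"` (plain DWT sub-bands, levels + 1 per channel).
#' @param tdpsd_lambda power-normalization exponent for the spectral moments,
#'   in (0, 1]. Default 0.1.
#' @param tdpsd_fusion logical; fuse the descriptor vector of the raw window
#'   with that of its log-squared counterpart via a cosine-style orientation
#'   measure (default TRUE).
#' @param length_normalize divide the extensive features (IAV, WL, wavelet
#'   energies) by window length; off by default because training pools
#'   several window lengths and standardization handles scale.
#' @return a `feature_config` list.
#' @export
feature_config <- function(zc_ssc_deadzone = 0, wavelet_levels = 5,
                           wavelet_variant = c("packet", "all_nodes", "dwt"),
                           tdpsd_lambda = 0.1, tdpsd_fusion = TRUE,
                           length_normalize = FALSE) {
  wavelet_variant <- match.arg(wavelet_variant)
  stopifnot(zc_ssc_deadzone >= 0, wavelet_levels >= 1,
            tdpsd_lambda > 0, tdpsd_lambda <= 1)
  structure(list(zc_ssc_deadzone = zc_ssc_deadzone,
                 wavelet_levels = wavelet_levels,
                 wavelet_variant = wavelet_variant,
                 tdpsd_lambda = tdpsd_lambda, tdpsd_fusion = tdpsd_fusion,
                 length_normalize = length_normalize),
            class = "feature_config")
}

.as_window <- function(w) {
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  w
}

#' Time-domain (Hudgins-style) features
#'
#' Per channel: integral absolute value IAV = sum |x|; waveform length
#' WL = sum |x[n+1] - x[n]|; zero crossings ZC (sign changes whose amplitude
#' step exceeds the dead zone); slope-sign changes SSC (local extrema with a
#' slope step exceeding the dead zone). Channel-major concatenation, 4 values
#' per channel.
#'
#' @param w window matrix (n_channels x L) or a vector for one channel.
#' @param cfg a [feature_config()].
#' @return named numeric vector, length 4 x n_channels.
#' @export
td_features <- function(w, cfg = feature_config()) {
  w <- .as_window(w)
  if (ncol(w) < 3L) stop("window too short for TD features (need >= 3 samples)")
  eps <- cfg$zc_ssc_deadzone
  out <- lapply(seq_len(nrow(w)), function(ch) {
    x <- w[ch, ]
    d <- diff(x)
    iav <- sum(abs(x))
    wl <- sum(abs(d))
    zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) > eps)
    s1 <- x[-c(1L, length(x))] - x[-c(length(x) - 1L, length(x))]
    s2 <- x[-c(1L, length(x))] - x[-c(1L, 2L)]
    ssc <- sum(s1 * s2 > 0 & (abs(s1) > eps | abs(s2) > eps))
    if (cfg$length_normalize) {
      iav <- iav / ncol(w)
      wl <- wl / ncol(w)
    }
    c(IAV = iav, WL = wl, ZC = zc, SSC = ssc)
  })
  v <- unlist(out)
  names(v) <- paste0("ch", rep(seq_len(nrow(w)), each = 4L), "_",
                     rep(c("IAV", "WL", "ZC", "SSC"), nrow(w)))
  v
}

#' Wavelet-packet energy features
#'
#' Per channel: the energy (sum of squared coefficients) of each node of a
#' 5-level wavelet-packet tree with the order-8 symlet and periodized
#' boundaries -- 32 terminal nodes per channel by default. Configurable
#' variants use all tree nodes or the plain DWT sub-bands instead.
#'
#' @inheritParams td_features
#' @return named numeric vector, length (nodes per channel) x n_channels.
#' @export
wavelet_energy_features <- function(w, cfg = feature_config()) {
  w <- .as_window(w)
  lev <- cfg$wavelet_levels
  if (ncol(w) < 2^lev) {
    stop(sprintf("window of %d samples too short for %d wavelet levels",
                 ncol(w), lev))
  }
  per_ch <- lapply(seq_len(nrow(w)), function(ch) {
    x <- w[ch, ]
    e <- switch(cfg$wavelet_variant,
      packet = vapply(wavelet_packet(x, lev), function(z) sum(z^2), 0),
      all_nodes = {
        nodes <- list(x)
        acc <- numeric(0)
        for (l in seq_len(lev)) {
          nxt <- vector("list", 2L * length(nodes))
          for (i in seq_along(nodes)) {
            nxt[[2L * i - 1L]] <- .wp_step(nodes[[i]], .sym8_dec_lo)
            nxt[[2L * i]] <- .wp_step(nodes[[i]], .sym8_dec_hi)
          }
          nodes <- nxt
          acc <- c(acc, vapply(nodes, function(z) sum(z^2), 0))
        }
        acc
      },
      dwt = vapply(.dwt_subbands(x, lev), function(z) sum(z^2), 0))
    if (cfg$length_normalize) e <- e / ncol(w)
    e
  })
  width <- length(per_ch[[1]])
  v <- unlist(per_ch)
  names(v) <- paste0("ch", rep(seq_len(nrow(w)), each = width), "_wp_node",
                     rep(seq_len(width), nrow(w)))
  v
}

# Six spectral descriptors of one channel from its time-domain moments.
.tdpsd_six <- function(x, lambda) {
  d1 <- diff(x)
  d2 <- diff(d1)
  m0 <- sqrt(sum(x^2))
  m2 <- sqrt(sum(d1^2))
  m4 <- sqrt(sum(d2^2))
  pw <- function(m) m^lambda / lambda
  m0 <- pw(m0); m2 <- pw(m2); m4 <- pw(m4)
  # log-magnitude convention: m2 can exceed m0 (e.g. wideband windows), so
  # the differences enter through their absolute value, as in the reference
  # descriptor family; a zero argument is a genuine domain violation.
  args <- abs(c(f1 = m0, f2 = m0 - m2, f3 = m0 - m4,
                f4 = m0 / sqrt(abs((m0 - m2) * (m0 - m4))),
                f5 = m2 / sqrt(m0 * m4),
                f6 = sum(abs(d1)) / sum(abs(d2))))
  if (any(!is.finite(args)) || any(args == 0)) {
    stop(paste("degenerate window for TD-PSD: a log argument is",
               "zero or non-finite (constant or near-constant signal?)"))
  }
  log(args)
}

#' Time-domain power-spectral descriptors (TD-PSD)
#'
#' Per channel, six descriptors of the window's power spectrum computed
#' entirely in the time domain from the root power of the signal and of its
#' first and second differences (m0, m2, m4, each power-normalized as
#' m^lambda / lambda): log of m0; of m0 - m2; of m0 - m4; a sparseness
#' measure m0 / sqrt((m0 - m2)(m0 - m4)); the irregularity factor
#' m2 / sqrt(m0 m4); and the waveform-length ratio sum|dx| / sum|ddx|.
#' With `tdpsd_fusion` the six descriptors `a` of the raw window and `b` of
#' its log-squared counterpart are combined elementwise into the orientation
#' measure -2 a_i b_i / (a_i^2 + b_i^2), which discards overall scale.
#'
#' @inheritParams td_features
#' @return named numeric vector, length 6 x n_channels.
#' @export
td_psd_features <- function(w, cfg = feature_config()) {
  w <- .as_window(w)
  if (ncol(w) < 3L) stop("window too short for TD-PSD (need >= 3 samples)")
  out <- lapply(seq_len(nrow(w)), function(ch) {
    x <- w[ch, ]
    a <- .tdpsd_six(x, cfg$tdpsd_lambda)
    if (isTRUE(cfg$tdpsd_fusion)) {
      b <- .tdpsd_six(log(x^2 + .Machine$double.eps), cfg$tdpsd_lambda)
      -2 * a * b / (a^2 + b^2)
    } else {
      a
    }
  })
  v <- unlist(out)
  names(v) <- paste0("ch", rep(seq_len(nrow(w)), each = 6L), "_",
                     rep(paste0("psd_f", 1:6), nrow(w)))
  v
}

#' Extract one feature family from a window
#'
#' @param w window matrix (n_channels x L).
#' @param family `"TD"`, `"WAVELET"` or `"TDPSD"`.
#' @param cfg a [feature_config()].
#' @return named numeric vector (channel-major).
#' @export
extract_features <- function(w, family = c("TDPSD", "TD", "WAVELET"),
                             cfg = feature_config()) {
  family <- match.arg(family)
  switch(family,
         TD = td_features(w, cfg),
         WAVELET = wavelet_energy_features(w, cfg),
         TDPSD = td_psd_features(w, cfg))
}
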