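# Periodized wavelet-packet transform with the order-8 symlet.
# Filter coefficients are the standard sym8 orthonormal decomposition pair.

.sym8_dec_lo <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
   0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
   0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
   0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
   0.0018899503327594609)

.sym8_dec_hi <- c(
  -0.0018899503327594609, -0.0003029205147213668, 0.01495225833704823,
   0.003808752013890615, -0.049137179673607506, -0.027219029917056003,
   0.05194583810770904, 0.3644418948353314, -0.7771857517005235,
   0.4813596512583722, 0.061273359067658524, -0.1432942383508097,
  -0.007607487324917605, 0.03169508781149298, 0.0005421323317911481,
  -0.0033824159510061256)

# One periodized analysis step: circular correlation with the filter followed
# by dyadic downsampling. Odd-length inputs are extended by one sample
# (repeating the last) first. For even N the two-channel bank is orthonormal,
# so energy is conserved exactly.
.wp_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(filt)
  idx <- outer(seq(0L, n - 2L, by = 2L), seq_len(L) - 1L, "+") %% n + 1L
  drop(matrix(x[idx], ncol = L) %*% filt)
}

#' Wavelet-packet coefficients at the terminal level
#'
#' Full wavelet-packet decomposition of a single-channel window with the
#' order-8 symlet and periodized boundaries. Returns the coefficient vectors
#' of the 2^levels terminal nodes in natural order (node 1 = repeated
#' low-pass = lowest frequency band).
#'
#' @param x numeric vector, length >= 2^levels.
#' @param levels decomposition depth (default 5, giving 32 terminal nodes).
#' @return list of 2^levels coefficient vectors.
#' @export
wavelet_packet <- function(x, levels = 5) {
  if (length(x) < 2^levels) {
    stop(sprintf("window of %d samples is too short for %d levels",
                 length(x), levels))
  }
  nodes <- list(x)
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2L * i - 1L]] <- .wp_step(nodes[[i]], .sym8_dec_lo)
      nxt[[2L * i]] <- .wp_step(nodes[[i]], .sym8_dec_hi)
    }
    nodes <- nxt
  }
  nodes
}

# DWT sub-band variant: only the approximation branch is split further,
# giving levels+1 terminal sub-bands (d1..d5, a5).
.dwt_subbands <- function(x, levels = 5) {
  out <- vector("list", levels + 1L)
  a <- x
  for (lev in seq_len(levels)) {
    out[[lev]] <- .wp_step(a, .sym8_dec_hi)
    a <- .wp_step(a, .sym8_dec_lo)
  }
  out[[levels + 1L]] <- a
  out
}
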