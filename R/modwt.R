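#' Maximal overlap discrete wavelet transform (MODWT)
#'
#' Non-decimated, shift-invariant wavelet decomposition with circular
#' boundary handling, used here to isolate QRS-band energy for R-peak
#' detection. The transform follows the standard pyramid algorithm: at level
#' `j` the (rescaled) scaling and wavelet filters are applied with stride
#' `2^(j-1)` to the level `j-1` scaling coefficients.
#'
#' @param x Numeric vector.
#' @param n_levels Decomposition depth `J`; `2^J` must not exceed `length(x)`.
#' @param wavelet Wavelet family; currently `"sym4"` (least-asymmetric
#'   Daubechies, 8 taps), the conventional choice for QRS detection.
#' @return For `modwt()`, a list with `W` (list of wavelet coefficient
#'   vectors, levels 1..J) and `V` (final scaling coefficients). For
#'   [modwt_mra()], a list of detail series `D1..DJ` plus the smooth `SJ`,
#'   each the length of `x`; they sum to `x` exactly.
#' @export
modwt <- function(x, n_levels, wavelet = "sym4") {
  stopifnot(is.numeric(x), n_levels >= 1, 2^n_levels <= length(x))
  f <- modwt_filters(wavelet)
  v <- as.numeric(x)
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    W[[j]] <- circular_filter(v, f$h, 2L^(j - 1L))
    v <- circular_filter(v, f$g, 2L^(j - 1L))
  }
  list(W = W, V = v, n_levels = n_levels, wavelet = wavelet, n = length(x))
}

#' @rdname modwt
#' @export
modwt_mra <- function(x, n_levels, wavelet = "sym4") {
  dec <- modwt(x, n_levels, wavelet)
  f <- modwt_filters(wavelet)
  n <- dec$n
  details <- vector("list", n_levels + 1L)
  for (j in seq_len(n_levels)) {
    details[[j]] <- inverse_from_level(dec$W[[j]], numeric(n), j, f)
  }
  details[[n_levels + 1L]] <- inverse_from_level(numeric(n), dec$V, n_levels, f)
  names(details) <- c(paste0("D", seq_len(n_levels)), paste0("S", n_levels))
  details
}

# One inverse pyramid pass starting from level-j coefficients (either the
# wavelet coefficients W with zero V, or vice versa), yielding the detail or
# smooth contribution at the data scale.
inverse_from_level <- function(w, v, j, f) {
  for (k in rev(seq_len(j))) {
    stride <- 2L^(k - 1L)
    wk <- if (k == j) w else numeric(length(v))
    v <- circular_filter_adj(wk, f$h, stride) +
      circular_filter_adj(v, f$g, stride)
  }
  v
}

# y[t] = sum_l f[l] x[(t - stride*(l-1)) mod n]
circular_filter <- function(x, f, stride) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (stride * (l - 1L)) %% n
    y <- y + f[l] * x[((idx - 1L - shift) %% n) + 1L]
  }
  y
}

# adjoint: y[t] = sum_l f[l] x[(t + stride*(l-1)) mod n]
circular_filter_adj <- function(x, f, stride) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (stride * (l - 1L)) %% n
    y <- y + f[l] * x[((idx - 1L + shift) %% n) + 1L]
  }
  y
}

modwt_filters <- function(wavelet = c("sym4", "haar")) {
  wavelet <- match.arg(wavelet)
  g <- switch(wavelet,
    sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
             0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333),
    haar = c(sqrt(0.5), sqrt(0.5))
  )
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  # MODWT filters are rescaled by sqrt(2)
  list(g = g / sqrt(2), h = h / sqrt(2))
}
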