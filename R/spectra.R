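# Largest-eigenvalue statistics of windowed covariance matrices of the
# tensor profile, their empirical spectral density, and the Tracy-Widom
# edge normalization.

#' Construct an eigenvalue sample
#'
#' Container for a collection of largest eigenvalues (one per sliding
#' window) whose empirical spectral density is analysed downstream.
#'
#' @param values Numeric vector of nonnegative eigenvalues.
#' @param N Covariance dimension the eigenvalues came from (NA if unknown,
#'   e.g. for feature-level synthetic samples).
#' @param window_length,stride Window geometry in frames (NA if not
#'   applicable).
#' @return An object of class `eigen_sample`.
#' @export
eigen_sample <- function(values, N = NA_integer_, window_length = NA_integer_,
                         stride = NA_integer_) {
  if (!is.numeric(values) || length(values) < 1) {
    stop_rube("`values` must be a non-empty numeric vector.", "input")
  }
  structure(
    list(values = as.numeric(values), N = N,
         window_length = window_length, stride = stride),
    class = "eigen_sample"
  )
}

#' @export
print.eigen_sample <- function(x, ...) {
  cat(sprintf(
    "<eigen_sample> %d largest eigenvalues (N = %s, window = %s, stride = %s)\n",
    length(x$values), x$N, x$window_length, x$stride
  ))
  print(summary(x$values))
  invisible(x)
}

#' @export
as_tibble.eigen_sample <- function(x, ...) {
  tibble(window = seq_along(x$values), value = x$values)
}

# Largest eigenvalue of X' X / (w - 1) without forming the covariance:
# power iteration on v -> X (X'v) / (w - 1), fixed-seed start vector.
lambda_max_power <- function(Xc, tol = 1e-12, max_iter = 1e4) {
  n <- nrow(Xc)
  w <- ncol(Xc)
  v <- with_seed_(104729L, rnorm(n))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    u <- as.numeric(Xc %*% crossprod(Xc, v)) / (w - 1)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    v_new <- u / nu
    lam_new <- sum(v_new * (Xc %*% crossprod(Xc, v_new))) / (w - 1)
    if (abs(lam_new - lam) <= tol * max(1, abs(lam_new))) return(lam_new)
    v <- v_new
    lam <- lam_new
  }
  lam
}

#' Largest eigenvalues over sliding covariance windows
#'
#' Slides a window of `window_length` frames with step `stride` along the
#' tensor profile; in each window the sample covariance of the pixel rows
#' is formed (rows centred within the window) and its largest eigenvalue
#' extracted by power iteration (tolerance 1e-12, at most 1e4 iterations,
#' fixed-seed start vector). The resulting collection — one
#' \eqn{\lambda_{max}} per window — is the sample whose empirical spectral
#' density the tail analysis characterises.
#'
#' @param tp A [tensor_profile] object or a numeric matrix (pixels x
#'   frames).
#' @param window_length Window length in frames (>= 2).
#' @param stride Step between consecutive windows in frames (>= 1).
#' @param n_pixels Optional number of pixel rows to subsample (evenly
#'   spaced) before the eigen-analysis; `NULL` keeps all rows. Smaller N
#'   speeds up desk-scale runs without changing the tail type.
#' @return An [eigen_sample] with `floor((T - window_length)/stride) + 1`
#'   values.
#' @export
windowed_lambda_max <- function(tp, window_length = 250, stride = 50,
                                n_pixels = NULL) {
  P <- if (inherits(tp, "tensor_profile")) tp$P else tp
  if (!is.matrix(P)) stop_rube("`tp` must be a tensor profile or matrix.", "input")
  check_number(window_length, "window_length", lower = 2, integerish = TRUE)
  check_number(stride, "stride", lower = 1, integerish = TRUE)
  T_len <- ncol(P)
  if (T_len < window_length) {
    stop_rube("Profile has fewer frames than one window.", "input")
  }
  if (!is.null(n_pixels) && n_pixels < nrow(P)) {
    keep <- unique(round(seq(1, nrow(P), length.out = n_pixels)))
    P <- P[keep, , drop = FALSE]
  }
  starts <- seq(1, T_len - window_length + 1, by = stride)
  vals <- purrr::map_dbl(starts, function(s) {
    Xw <- P[, s:(s + window_length - 1), drop = FALSE]
    Xc <- Xw - rowMeans(Xw)
    lambda_max_power(Xc)
  })
  eigen_sample(pmax(vals, 0), N = nrow(P),
               window_length = window_length, stride = stride)
}

#' Empirical spectral density
#'
#' Normalized histogram estimate of the density of a collection of
#' (largest) eigenvalues, with Freedman-Diaconis binning by default. The
#' histogram densities integrate to 1.
#'
#' @param data Numeric vector, [eigen_sample], or data frame with `value`.
#' @param bins Number of bins, or `"FD"` (default) for Freedman-Diaconis.
#' @return A tibble of class `esd` with columns `bin_left`, `bin_right`,
#'   `bin_center`, `density`, `count`.
#' @export
esd <- function(data, bins = "FD") {
  x <- as_esd_values(data)
  if (diff(range(x)) == 0) {
    out <- tibble(
      bin_left = x[1] - 0.5, bin_right = x[1] + 0.5,
      bin_center = x[1], density = 1, count = length(x)
    )
  } else {
    h <- if (identical(bins, "FD")) {
      graphics::hist(x, breaks = "FD", plot = FALSE)
    } else {
      check_number(bins, "bins", lower = 1, integerish = TRUE)
      graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                     plot = FALSE)
    }
    out <- tibble(
      bin_left = head(h$breaks, -1), bin_right = tail(h$breaks, -1),
      bin_center = h$mids, density = h$density, count = h$counts
    )
  }
  attr(out, "values") <- x
  class(out) <- c("esd", class(out))
  out
}

#' Tracy-Widom edge normalization
#'
#' Normalizes largest eigenvalues to the Tracy-Widom scale:
#' \deqn{\xi = \sqrt{2}\, N^{1/6} (\lambda_{max} - \sqrt{2N})}
#' where `N` is the matrix dimension. The map is strictly increasing in
#' \eqn{\lambda_{max}} for fixed N.
#'
#' @param lambda_max Numeric vector of largest eigenvalues.
#' @param N Matrix dimension (>= 1).
#' @return Numeric vector of normalized values \eqn{\xi}.
#' @export
#' @examples
#' tw_normalize(sqrt(128) + 1, N = 64)  # sqrt(2) * 2
tw_normalize <- function(lambda_max, N) {
  check_number(N, "N", lower = 1, integerish = TRUE)
  if (!is.numeric(lambda_max)) stop_rube("`lambda_max` must be numeric.", "param")
  sqrt(2) * N^(1 / 6) * (lambda_max - sqrt(2 * N))
}
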