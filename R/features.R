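# Feature-signal extraction: transforms of the preprocessed ECG in
# which QRS complexes stand out for threshold-based detection.
#
# The per-lead chain follows Pan-Tompkins: narrow band-pass (5-15 Hz),
# five-point derivative, squaring, and moving-window integration. Lead
# combinations: squared-lead sum (RMS), combinational product, PCA
# projection on the dominant covariance eigenvector, and ICA component
# selection by maximal kurtosis.

.pt_bandpass <- function(x, fs, lo = 5, hi = 15) {
  if (fs < 40) stop("sampling rate too low for the 5-15 Hz QRS band-pass")
  flt <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
  .filtfilt_pad(flt, x, np = round(3 * fs / lo))
}

# centered five-point derivative, kernel (-1,-2,0,2,1)/8 scaled by fs
.pt_derivative <- function(x, fs) {
  n <- length(x)
  xp <- c(rep(x[1L], 2L), x, rep(x[n], 2L))
  y <- stats::filter(xp, c(1, 2, 0, -2, -1), sides = 2)
  as.numeric(y[3L:(n + 2L)]) * fs / 8
}

#' Pan-Tompkins feature chain for one lead
#'
#' Band-pass (5-15 Hz), five-point derivative, squaring, and a 150-ms
#' moving-window integration. The output is nonnegative with one
#' dominant hump per QRS complex.
#'
#' @param lead Numeric vector, one preprocessed ECG lead in mV.
#' @param fs Sampling rate in Hz (>= 40).
#' @param mwi_ms Integration window in milliseconds (default 150).
#' @return Nonnegative numeric vector, same length as `lead`.
#' @export
pt_filter_lead <- function(lead, fs, mwi_ms = 150) {
  d <- .pt_derivative(.pt_bandpass(lead, fs), fs)
  w <- max(1L, as.integer(round(mwi_ms * fs / 1000)))
  .moving_mean(d * d, w)
}

#' Band-pass + derivative filtering of all leads
#'
#' The linear part of the Pan-Tompkins chain (no squaring or
#' integration), applied per lead. This filtered lead set is the signal
#' the lead-combination features and the coarse peak search operate on.
#'
#' @param signal A preprocessed [multilead_signal].
#' @return An object of class `filtered_lead_set` with fields `xf`
#'   (n x L matrix) and `fs`.
#' @export
derivative_filter_leads <- function(signal) {
  fs <- signal$fs
  xf <- apply(signal$samples, 2L, function(x)
    .pt_derivative(.pt_bandpass(x, fs), fs))
  structure(list(xf = xf, fs = fs, lead_names = signal$lead_names),
            class = "filtered_lead_set")
}

#' Squared-lead-sum (RMS) feature
#'
#' Combines all filtered leads into a single nonnegative feature by
#' summing the squared filtered samples across leads:
#' `y[n] = sum_l xf[n, l]^2`.
#'
#' @param xf A [derivative_filter_leads()] result.
#' @return A [feature_signal] with method `"RMS"`.
#' @export
rms_feature <- function(xf) {
  feature_signal(rowSums(xf$xf^2), "RMS", xf$fs)
}

#' Combinational lead-product feature
#'
#' For each lead, multiplies the filtered lead by the product of all
#' other filtered leads: `y[n, i] = xf[n, i] * prod_{j != i} xf[n, j]`.
#' Note that this equals the product over all leads for every `i`, so
#' all columns are identical; the per-lead form is kept for detection
#' plumbing. The sign is indefinite; detection thresholds `|y|`.
#'
#' @param xf A [derivative_filter_leads()] result with L >= 2 leads.
#' @return A [feature_signal] with method `"PROD"` (n x L matrix).
#' @export
product_feature <- function(xf) {
  L <- ncol(xf$xf)
  if (L < 2L) stop("the combinational product feature requires >= 2 leads")
  p <- xf$xf[, 1L]
  for (j in 2:L) p <- p * xf$xf[, j]
  feature_signal(matrix(p, nrow = length(p), ncol = L), "PROD", xf$fs)
}

#' PCA lead-reduction feature
#'
#' Projects the leads onto the eigenvector of the lead covariance
#' matrix with the largest eigenvalue and squares the projection. With
#' leads carrying different projections of the same cardiac activity,
#' the dominant component concentrates QRS energy.
#'
#' @param signal A preprocessed [multilead_signal] with L >= 2.
#' @return A [feature_signal] with method `"PCA"`; the eigenvalues (in
#'   descending order) are attached as field `eigenvalues`.
#' @export
pca_feature <- function(signal) {
  if (n_leads(signal) < 2L) stop("PCA feature requires >= 2 leads")
  x <- scale(signal$samples, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  proj <- as.numeric(x %*% eg$vectors[, 1L])
  out <- feature_signal(proj^2, "PCA", signal$fs)
  out$eigenvalues <- eg$values
  out
}

.kurtosis <- function(z) {
  z <- z - mean(z)
  m2 <- mean(z^2)
  if (m2 <= .Machine$double.eps) return(-3)
  mean(z^4) / m2^2 - 3
}

# symmetric FastICA with tanh contrast on whitened data; deterministic
# given `seed`. Returns the unmixing applied to the centered data, or
# NULL on convergence failure.
.fast_ica <- function(x, seed = 1L, max_iter = 200L, tol = 1e-6) {
  L <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  d <- pmax(eg$values, .Machine$double.eps)
  K <- eg$vectors %*% diag(1 / sqrt(d), L)     # whitening matrix
  z <- xc %*% K                                 # n x L, unit covariance
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  W <- matrix(stats::rnorm(L * L), L, L)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(max_iter)) {
    u <- z %*% t(W)
    g <- tanh(u)
    gp <- 1 - g^2
    W1 <- t(g) %*% z / nrow(z) - diag(colMeans(gp), L) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      return(list(sources = z %*% t(W), converged = TRUE))
    }
  }
  NULL
}

#' ICA lead-reduction feature
#'
#' Estimates statistically independent components from the lead mixture
#' (FastICA, tanh contrast, symmetric decorrelation), ranks them by
#' descending kurtosis, and squares the most super-Gaussian component —
#' the sparse spiky QRS train has far higher kurtosis than noise or
#' baseline components. The squaring also removes the ICA sign
#' ambiguity. Deterministic for a given `seed`; on convergence failure
#' the PCA feature is returned with a warning.
#'
#' @param signal A preprocessed [multilead_signal] with L >= 2.
#' @param seed Integer seed for the random unmixing initialization.
#' @return A [feature_signal] with method `"ICA"`; the per-component
#'   kurtoses (descending) are attached as field `kurtosis`, and the
#'   selected source as field `source`.
#' @export
ica_feature <- function(signal, seed = 1L) {
  if (n_leads(signal) < 2L) stop("ICA feature requires >= 2 leads")
  res <- .fast_ica(signal$samples, seed = seed)
  if (is.null(res)) {
    warning("ICA failed to converge; falling back to the PCA feature")
    return(pca_feature(signal))
  }
  kurt <- apply(res$sources, 2L, .kurtosis)
  ord <- order(kurt, decreasing = TRUE)
  src <- res$sources[, ord[1L]]
  out <- feature_signal(src^2, "ICA", signal$fs)
  out$kurtosis <- kurt[ord]
  out$source <- src
  out
}

# lead with the lowest time-local variance ratio (95th percentile of
# the sliding variance over its median): the "lowest noise content"
# criterion for the single-lead Pan-Tompkins variant
select_cleanest_lead <- function(signal, win_s = 0.2) {
  w <- max(3L, as.integer(round(win_s * signal$fs)))
  ratios <- apply(signal$samples, 2L, function(x) {
    m1 <- .moving_mean(x, w)
    m2 <- .moving_mean(x * x, w)
    v <- pmax(0, m2 - m1 * m1)
    md <- stats::median(v)
    if (md <= .Machine$double.eps) return(Inf)
    stats::quantile(v, 0.95, names = FALSE) / md
  })
  which.min(ratios)
}

#' Compute a feature signal by name
#'
#' @param signal A preprocessed [multilead_signal].
#' @param method One of `"ptlead"` (full Pan-Tompkins chain per lead,
#'   the input to the fusion rules), `"pt"` (single cleanest lead),
#'   `"rms"`, `"prod"`, `"pca"`, `"ica"`.
#' @param seed Seed for ICA.
#' @return A [feature_signal].
#' @export
extract_feature <- function(signal,
                            method = c("ptlead", "pt", "rms", "prod",
                                       "pca", "ica"),
                            seed = 1L) {
  method <- match.arg(method)
  fs <- signal$fs
  switch(method,
    ptlead = feature_signal(
      apply(signal$samples, 2L, pt_filter_lead, fs = fs), "PTLEAD", fs),
    pt = {
      i <- select_cleanest_lead(signal)
      out <- feature_signal(pt_filter_lead(signal$samples[, i], fs),
                            "PT", fs)
      out$lead <- i
      out
    },
    rms = rms_feature(derivative_filter_leads(signal)),
    prod = product_feature(derivative_filter_leads(signal)),
    pca = pca_feature(signal),
    ica = ica_feature(signal, seed = seed))
}
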