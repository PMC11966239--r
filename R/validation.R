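#' Fourier shell correlation of two volumes
#'
#' Per radial shell s of the 3D DFT:
#' `FSC(s) = Re(sum(F_A * Conj(F_B))) / sqrt(sum|F_A|^2 * sum|F_B|^2)`.
#' Shells are unit-voxel-width bins of the rounded integer frequency
#' radius; the DC term belongs to shell 0. No masking or phase-
#' randomization correction is applied (maps are compared as given).
#'
#' @param A,B Cubic numeric arrays of the same shape.
#' @param pixel_size Voxel size in Angstrom.
#' @return A `cf_fsc` object: data frame columns `shell`, `freq` (1/A),
#'   `fsc`, plus attributes `pixel_size`, `n`.
#' @export
fsc <- function(A, B, pixel_size = 1) {
  dA <- dim(A)
  if (!identical(dA, dim(B))) stop("volumes must have the same shape")
  if (length(dA) != 3 || length(unique(dA)) != 1)
    stop("volumes must be cubic")
  n <- dA[1]
  FA <- stats::fft(A)
  FB <- stats::fft(B)
  k <- c(0:(ceiling(n / 2) - 1), -floor(n / 2):-1)
  kx <- array(k, dim = dA)
  ky <- aperm(kx, c(2, 1, 3))
  kz <- aperm(kx, c(3, 2, 1))
  shell <- round(sqrt(kx^2 + ky^2 + kz^2))
  nshell <- floor(n / 2)
  sel <- shell <= nshell
  sh <- as.integer(shell[sel]) + 1L
  num <- rowsum(Re(FA[sel] * Conj(FB[sel])), sh)
  pa <- rowsum(abs(FA[sel])^2, sh)
  pb <- rowsum(abs(FB[sel])^2, sh)
  denom <- sqrt(pa * pb)
  vals <- ifelse(denom > 0, num / denom, 0)
  out <- data.frame(shell = 0:nshell,
                    freq = (0:nshell) / (n * pixel_size),
                    fsc = as.numeric(vals))
  structure(out, class = c("cf_fsc", "data.frame"),
            pixel_size = pixel_size, n = n)
}

#' Resolution at an FSC threshold
#'
#' The first frequency at which the curve drops below the threshold,
#' linearly interpolated between shells, reported as a real-space distance
#' `1/frequency` in Angstrom. If the curve never crosses, the Nyquist
#' resolution `2 * pixel_size` is returned with attribute
#' `crossed = FALSE`. The readout is never finer than Nyquist.
#'
#' @param curve A `cf_fsc` from [fsc()].
#' @param threshold FSC threshold (0.5 against a reference ground truth,
#'   0.143 between half-maps are the conventional choices).
#' @return Resolution in Angstrom with attribute `crossed`.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "cf_fsc"))
  ps <- attr(curve, "pixel_size")
  nyq <- 2 * ps
  below <- which(curve$fsc < threshold)
  below <- below[below > 1]  # shell 0 is the DC term
  if (length(below) == 0)
    return(structure(nyq, crossed = FALSE))
  i <- below[1]
  f1 <- curve$freq[i - 1]; f2 <- curve$freq[i]
  v1 <- curve$fsc[i - 1]; v2 <- curve$fsc[i]
  fc <- if (v1 == v2) f2 else f1 + (v1 - threshold) / (v1 - v2) * (f2 - f1)
  if (fc <= 0) return(structure(nyq, crossed = FALSE))
  structure(max(1 / fc, nyq), crossed = TRUE)
}

#' Real-space Pearson correlation of two volumes
#'
#' @param A,B Numeric arrays of the same shape.
#' @param mask Optional logical/numeric array; only voxels where
#'   `mask > 0` enter the correlation.
#' @return Pearson correlation coefficient.
#' @export
volume_correlation <- function(A, B, mask = NULL) {
  if (!identical(dim(A), dim(B))) stop("volumes must have the same shape")
  a <- as.numeric(A)
  b <- as.numeric(B)
  if (!is.null(mask)) {
    keep <- as.numeric(mask) > 0
    a <- a[keep]
    b <- b[keep]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: correlation undefined")
  stats::cor(a, b)
}

#' Build a 2x2 confusion matrix
#'
#' Actual class on rows, predicted class on columns, positive class first.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `cf_confusion` matrix.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cm <- matrix(c(tp, fp, fn, tn), 2, 2,
               dimnames = list(actual = c("+", "-"),
                               predicted = c("+", "-")))
  if (any(cm < 0)) stop("counts must be non-negative")
  if (sum(cm) == 0) stop("empty confusion matrix")
  structure(cm, class = c("cf_confusion", class(cm)))
}

#' Confusion matrix from label vectors
#'
#' @param truth,labels 0/1 integer vectors (1 = positive class).
#' @return A `cf_confusion` matrix.
#' @export
confusion_from_labels <- function(truth, labels) {
  confusion_matrix(sum(truth == 1 & labels == 1),
                   sum(truth == 1 & labels == 0),
                   sum(truth == 0 & labels == 1),
                   sum(truth == 0 & labels == 0))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and precision `TP/(TP+FP)`, reported as
#' percentages rounded to 2 decimals.
#'
#' @param cm A `cf_confusion` from [confusion_matrix()].
#' @return Named numeric vector (percent): accuracy, sensitivity,
#'   specificity, precision.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "cf_confusion"))
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- c(accuracy = tp + fn + fp + tn, sensitivity = tp + fn,
           specificity = tn + fp, precision = tp + fp)
  zero <- names(den)[den == 0]
  if (length(zero) > 0)
    stop("undefined metric (zero denominator): ",
         paste(zero, collapse = ", "))
  round(100 * c(accuracy = (tp + tn) / (tp + fn + fp + tn),
                sensitivity = tp / (tp + fn),
                specificity = tn / (tn + fp),
                precision = tp / (tp + fp)), 2)
}

#' Write an FSC curve to CSV
#'
#' @param curve A `cf_fsc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
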