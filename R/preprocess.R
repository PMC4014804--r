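#' Convert beta-values to M-values
#'
#' The M-value is the logit2 transform `M = log2(beta / (1 - beta))`. Beta
#' values are clamped to `[eps, 1 - eps]` before the transform so that fully
#' (un)methylated sites map to large finite M-values instead of infinities.
#'
#' @param beta Numeric vector or matrix of methylation fractions in `[0, 1]`.
#' @param eps Clamp applied before the logit; default `1e-6`.
#' @return Object of the same shape as `beta` holding M-values.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  out
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Methylation fractions in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) dim(out) <- dim(m)
  out
}

#' Locate the unmethylated and methylated density peaks of an M-value sample
#'
#' Fits a Gaussian kernel density (Silverman bandwidth, 512-point grid over
#' `grid_range`) to one sample's M-values and reports the density argmax on the
#' negative axis (unmethylated peak) and on the positive axis (methylated
#' peak). Both modes must exist: 450k-style data are bimodal in M space.
#'
#' @param m Numeric vector of M-values for one sample and one probe design
#'   type; at least 100 finite values with both signs represented.
#' @param grid_range Numeric length-2, grid limits in M units; default
#'   `c(-8, 8)`.
#' @param n_grid Number of grid points for the density evaluation.
#' @return List with elements `unmeth` (< 0) and `meth` (> 0), the two peak
#'   positions in M units.
#' @details Signals a condition of class `methylall_peak_not_found` when one
#'   side of the axis carries no values, so callers can fall back to leaving
#'   the sample uncorrected.
#' @export
find_density_peaks <- function(m, grid_range = c(-8, 8), n_grid = 512) {
  m <- m[is.finite(m)]
  if (length(m) < 100) {
    stop(peak_not_found_condition("fewer than 100 finite M-values"))
  }
  if (!any(m < 0) || !any(m > 0)) {
    stop(peak_not_found_condition("M-values do not span both signs"))
  }
  d <- stats::density(m, bw = "nrd0", n = n_grid,
                      from = grid_range[1], to = grid_range[2])
  neg <- d$x < 0
  pos <- d$x > 0
  if (!any(neg) || !any(pos)) {
    stop(peak_not_found_condition("density grid does not span both signs"))
  }
  unmeth <- d$x[neg][which.max(d$y[neg])]
  meth <- d$x[pos][which.max(d$y[pos])]
  if (max(d$y[neg]) <= 0 || max(d$y[pos]) <= 0) {
    stop(peak_not_found_condition("no density mass on one side of zero"))
  }
  list(unmeth = unmeth, meth = meth)
}

peak_not_found_condition <- function(msg) {
  structure(
    class = c("methylall_peak_not_found", "error", "condition"),
    list(message = paste0("peak not found: ", msg), call = sys.call(-1))
  )
}

#' Peak-based correction of type II probe values for one sample
#'
#' Rescales the type II M-value distribution of a single sample so that its
#' unmethylated and methylated density peaks coincide with the type I peaks of
#' the same sample. M-values below zero are multiplied by
#' `unmeth_peak_I / unmeth_peak_II`, M-values at or above zero by
#' `meth_peak_I / meth_peak_II`, and the result is mapped back to the beta
#' scale. Type I values are never altered.
#'
#' @param beta_I Beta-values of the sample's type I probes.
#' @param beta_II Beta-values of the sample's type II probes.
#' @param eps Clamp used by the logit transform.
#' @return Numeric vector of corrected type II beta-values (same order as
#'   `beta_II`). If a peak cannot be located on either design type the input is
#'   returned unchanged with a warning.
#' @export
peak_correct_sample <- function(beta_I, beta_II, eps = 1e-6) {
  stopifnot(length(beta_I) > 0, length(beta_II) > 0)
  peaks <- tryCatch({
    list(I = find_density_peaks(beta_to_m(beta_I[!is.na(beta_I)], eps)),
         II = find_density_peaks(beta_to_m(beta_II[!is.na(beta_II)], eps)))
  }, methylall_peak_not_found = function(e) NULL)
  if (is.null(peaks)) {
    warning("peak not found for one design type; sample left uncorrected")
    return(beta_II)
  }
  m <- beta_to_m(beta_II, eps)
  scale_neg <- peaks$I$unmeth / peaks$II$unmeth
  scale_pos <- peaks$I$meth / peaks$II$meth
  m_corr <- ifelse(m < 0, m * scale_neg, m * scale_pos)
  out <- m_to_beta(m_corr)
  out[is.na(beta_II)] <- NA_real_
  out
}

#' Peak-based correction of a whole beta matrix
#'
#' Applies [peak_correct_sample()] column by column, using the probe design
#' types recorded in the annotation. Correction is strictly per sample; no
#' cross-sample normalization is performed.
#'
#' @param beta Probe-by-sample beta matrix with probe ids as rownames.
#' @param annotation Probe annotation data frame with columns `IlmnID` and
#'   `Infinium_Design_Type` (`"I"` / `"II"`).
#' @param eps Clamp used by the logit transform.
#' @return List with `beta`, the corrected matrix, and `qc`, a per-sample data
#'   frame of type I / type II peak positions before and after correction
#'   (NA where peaks could not be located).
#' @export
peak_correct <- function(beta, annotation, eps = 1e-6) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  design <- annotation$Infinium_Design_Type[match(rownames(beta), annotation$IlmnID)]
  if (anyNA(design)) stop("annotation is missing design types for some probes")
  is2 <- design == "II"
  if (!any(is2) || all(is2)) {
    warning("only one design type present; matrix returned unchanged")
    return(list(beta = beta, qc = NULL))
  }
  out <- beta
  qc <- vector("list", ncol(beta))
  for (j in seq_len(ncol(beta))) {
    b1 <- beta[!is2, j]
    b2 <- beta[is2, j]
    corrected <- suppressWarnings(peak_correct_sample(b1, b2, eps))
    out[is2, j] <- corrected
    pk <- function(x) tryCatch(find_density_peaks(beta_to_m(x[!is.na(x)], eps)),
                               methylall_peak_not_found = function(e) {
                                 list(unmeth = NA_real_, meth = NA_real_)
                               })
    p1 <- pk(b1); p2 <- pk(b2); p2c <- pk(corrected)
    qc[[j]] <- data.frame(
      sample = colnames(beta)[j],
      typeI_unmeth = p1$unmeth, typeI_meth = p1$meth,
      typeII_unmeth = p2$unmeth, typeII_meth = p2$meth,
      typeII_unmeth_corrected = p2c$unmeth, typeII_meth_corrected = p2c$meth,
      stringsAsFactors = FALSE
    )
  }
  list(beta = out, qc = do.call(rbind, qc))
}

#' Filter probes to the analysis universe
#'
#' Drops probes on the X and Y chromosomes and probes whose hybridization is
#' affected by genetic variation (SNP flag), mirroring the standard 450k
#' analysis universe. Input order is preserved.
#'
#' @param annotation Probe annotation data frame with columns `IlmnID`, `CHR`
#'   and `SNP_flag` (logical or 0/1).
#' @return Character vector of retained probe ids, in annotation order.
#' @export
filter_probes <- function(annotation) {
  stopifnot(all(c("IlmnID", "CHR", "SNP_flag") %in% names(annotation)))
  chr <- toupper(sub("^CHR", "", toupper(as.character(annotation$CHR))))
  sexchr <- chr %in% c("X", "Y")
  snp <- as.logical(annotation$SNP_flag)
  snp[is.na(snp)] <- FALSE
  keep <- !sexchr & !snp
  if (!any(keep)) warning("all probes removed by filtering")
  annotation$IlmnID[keep]
}
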