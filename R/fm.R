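# FM-dye vesicle-turnover quantification.

#' Releasable-fluorescence difference image
#'
#' `deltaF = F1 - F2`, pixelwise, clipped at zero (unloading cannot exceed
#' loading except through noise). The pair must be registered and share
#' shape and pixel size.
#'
#' @param F1,F2 Loading and unloading 2D [image_stack()]s.
#' @return The deltaF [image_stack()].
#' @export
delta_f <- function(F1, F2) {
  stopifnot(inherits(F1, "ImageStack"), inherits(F2, "ImageStack"))
  if (!all(dim(F1$data) == dim(F2$data))) {
    stop_mgs("F1 and F2 have different shapes",
             class = "mgsynapse_validation_error")
  }
  image_stack(pmax(F1$data - F2$data, 0), theta = F1$theta, rho = F1$rho,
              channel = paste0("deltaF(", F1$channel, ")"))
}

#' Functional terminal density N5AP
#'
#' Number of stimulation-induced FM(+) puncta per unit MAP2(+) dendritic
#' area: `N5AP = #FM5AP / A`.
#'
#' @param delta_puncta [puncta_set()] detected on the deltaF image.
#' @param A Dendritic area in square micron (must be positive).
#' @return Density per square micron.
#' @export
functional_density <- function(delta_puncta, A) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop_mgs("density undefined: dendritic area must be positive",
             class = "mgsynapse_density_error")
  }
  nrow(delta_puncta) / A
}

#' Aggregate per-AOI values to coverslip and condition level
#'
#' AOIs are averaged within each coverslip, then the condition is summarized
#' as the mean +/- SEM over coverslip means — the hierarchical averaging
#' used for every per-area statistic here.
#'
#' @param values Per-AOI numeric values.
#' @param coverslip Parallel coverslip identifier.
#' @return `list(coverslip_means =, mean =, sem =, n_coverslips =)`.
#' @export
aggregate_condition <- function(values, coverslip) {
  stopifnot(length(values) == length(coverslip))
  cs <- tapply(values, coverslip, mean)
  list(coverslip_means = cs, mean = mean(cs), sem = sem(as.numeric(cs)),
       n_coverslips = length(cs))
}

#' Fraction of maximally-releasing terminals responsive to 5AP bursts
#'
#' Matches the 5AP-induced puncta against the 600AP-induced puncta in a
#' common frame; the functional fraction is the share of 600AP(+) terminals
#' hit by a 5AP punctum.
#'
#' @param p5,p600 [puncta_set()]s from the 5AP and 600AP deltaF images.
#' @param radius Matching radius (micron).
#' @return Fraction in `[0, 1]`.
#' @export
colocalize_stims <- function(p5, p600, radius = 0.5) {
  if (nrow(p600) == 0L) {
    stop_mgs("fraction undefined: no 600AP-responsive puncta",
             class = "mgsynapse_density_error")
  }
  if (nrow(p5) == 0L) return(0)
  m <- match_puncta(p5, p600, radius = radius)
  nrow(m$pairs) / nrow(p600)
}

#' Classify structural terminals as functional or nonfunctional
#'
#' A structural (e.g. SYP-positive) punctum is functional iff a 5AP deltaF
#' punctum lies within `radius`; otherwise it is a nonfunctional (silent)
#' terminal — structurally present but with no detectable release after the
#' 30-AP bursting input (release probability below ~0.04).
#'
#' @param structural [puncta_set()] of structural terminals.
#' @param p5 [puncta_set()] from the 5AP deltaF image, same frame.
#' @param radius Matching radius (micron).
#' @return The structural table with logical column `functional` and
#'   character column `label`.
#' @export
classify_terminals <- function(structural, p5, radius = 0.5) {
  structural$functional <- FALSE
  if (nrow(structural) > 0L && nrow(p5) > 0L) {
    m <- match_puncta(structural, p5, radius = radius)
    structural$functional[m$pairs$i] <- TRUE
  }
  structural$label <- ifelse(structural$functional, "functional",
                             "nonfunctional")
  structural
}
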