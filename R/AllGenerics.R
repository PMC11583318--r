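#' @import methods
#' @importFrom stats median sd lm coef ppois qpois rpois rlnorm rnorm runif
#'   prcomp cov cor dist hclust qchisq quantile qlnorm complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom BiocGenerics counts
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' @export
BiocGenerics::counts

#' Number of dwell intervals in an acquisition
#'
#' @param x an [AcquisitionSettings-class] or [TimeTrace-class] object.
#' @return Integer dwell count, `floor(acquisition_time / dwell_time)`.
#' @export
setGeneric("nDwells", function(x) standardGeneric("nDwells"))

#' Transport efficiency value
#'
#' @param object a [TransportEfficiency-class] object.
#' @return The efficiency as a fraction in (0, 1].
#' @export
setGeneric("eta", function(object) standardGeneric("eta"))

#' Calibration slope (sensitivity)
#'
#' @param object an [IonicCalibration-class] object.
#' @return Slope in counts per dwell per (ug/L).
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' Calibration intercept
#'
#' @param object an [IonicCalibration-class] object.
#' @return Intercept in counts per dwell.
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))
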