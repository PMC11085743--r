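#' @keywords internal
"_PACKAGE"

# Indicator panel layout shared across modules. Orientation +1 means
# higher-is-better (protective), -1 means lower-is-better (injury marker).
.INDICATORS <- c("viability", "ldh", "atp", "ros")
.ORIENTATION <- c(viability = 1, ldh = -1, atp = 1, ros = -1)

#' Bioactivity indicator names and orientations
#'
#' The four cell-injury indicators the pipeline models: MTT cell viability,
#' lactate dehydrogenase (LDH) release, ATP production and reactive oxygen
#' species (ROS) level. Orientation is +1 where a larger value means more
#' protection (viability, ATP) and -1 where a larger value means more injury
#' (LDH, ROS).
#'
#' @return Named numeric vector of +1/-1 orientations, names are the
#'   indicator ids in panel column order.
#' @export
#' @examples
#' indicator_orientations()
indicator_orientations <- function() .ORIENTATION

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# scalar checks used by the config constructors
check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config(field, "must be a single non-negative number")
  as.numeric(x)
}
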