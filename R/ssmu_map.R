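#' Small-scale management unit (SSMU) map
#'
#' The spatial skeleton of the model arena: an ordered set of SSMUs, each with
#' a surface area, a statistical-subarea label, and a flag saying whether it
#' lies inside the candidate marine protected area (MPA).
#'
#' @param ssmu_ids character or integer vector of unique SSMU identifiers,
#'   in arena order.
#' @param areas numeric vector of SSMU surface areas in square metres;
#'   strictly positive.
#' @param subarea character vector of subarea codes (e.g. "48.1", "48.2",
#'   "48.3"), one per SSMU.
#' @param mpa_mask logical vector, TRUE for SSMUs inside the MPA. Defaults to
#'   all-FALSE (no MPA delineated).
#' @return an object of class `ssmu_map`.
#' @export
ssmu_map <- function(ssmu_ids, areas, subarea,
                     mpa_mask = rep(FALSE, length(ssmu_ids))) {
  m <- structure(
    list(ssmu_ids = as.character(ssmu_ids),
         areas = as.numeric(areas),
         subarea = as.character(subarea),
         mpa_mask = as.logical(mpa_mask)),
    class = "ssmu_map")
  problems <- check_ssmu_map(m)
  if (length(problems)) stopf("invalid ssmu_map:\n- %s",
                              paste(problems, collapse = "\n- "))
  m
}

check_ssmu_map <- function(m) {
  p <- character(0)
  n <- length(m$ssmu_ids)
  if (n < 1) p <- c(p, "ssmu_ids is empty")
  if (anyDuplicated(m$ssmu_ids)) p <- c(p, "ssmu_ids are not unique")
  if (length(m$areas) != n) p <- c(p, "areas length differs from ssmu_ids")
  if (any(!is.finite(m$areas)) || any(m$areas <= 0))
    p <- c(p, "areas must be finite and strictly positive")
  if (length(m$subarea) != n) p <- c(p, "subarea length differs from ssmu_ids")
  if (length(m$mpa_mask) != n || anyNA(m$mpa_mask))
    p <- c(p, "mpa_mask must be a logical vector with one value per SSMU")
  p
}

n_ssmu <- function(x) {
  if (inherits(x, "ssmu_map")) length(x$ssmu_ids)
  else length(x$ssmu_map$ssmu_ids)
}

#' @export
print.ssmu_map <- function(x, ...) {
  cat(sprintf("SSMU map: %d units in subareas {%s}; %d inside MPA\n",
              length(x$ssmu_ids), paste(unique(x$subarea), collapse = ", "),
              sum(x$mpa_mask)))
  invisible(x)
}
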