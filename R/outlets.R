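#' Outlet flow split
#'
#' Bookkeeping for multi-outlet flow fractions. Each entry is a named
#' outlet with a per-vessel percentage and a bilateral flag; a bilateral
#' entry represents a left/right pair and counts twice in the mass balance.
#' A complete split's expanded total must equal 100% (within 0.01%).
#'
#' @param outlets tibble/data frame with columns `outlet` (character),
#'   `fraction` (percent per vessel; `NA` allowed for one unresolved
#'   outlet), `bilateral` (logical).
#' @param check require the expanded total to close at 100% (set FALSE for
#'   partial splits destined for [complete_split()]).
#' @return tibble of class `flow_split`.
#' @export
flow_split <- function(outlets, check = TRUE) {
  out <- tibble::as_tibble(outlets)
  stopifnot(all(c("outlet", "fraction", "bilateral") %in% names(out)))
  if (anyDuplicated(out$outlet)) stop("duplicate outlet names")
  if (any(out$fraction < 0, na.rm = TRUE)) stop("fractions must be >= 0")
  if (check) {
    if (anyNA(out$fraction)) stop("split is incomplete (NA fraction)")
    tot <- expanded_total(out)
    if (abs(tot - 100) > 0.01) {
      stop(sprintf("expanded fractions total %.4f%%, not 100%%", tot))
    }
  }
  class(out) <- c("flow_split", class(out))
  out
}

expanded_total <- function(split) {
  sum(split$fraction * ifelse(split$bilateral, 2, 1), na.rm = TRUE)
}

#' Resolve the one missing fraction of a flow split
#'
#' With exactly one outlet's fraction unknown, assigns it the remainder to
#' 100% of the expanded (bilateral-counted-twice) total.
#'
#' @param split a partial [flow_split()] (built with `check = FALSE`) with
#'   exactly one `NA` fraction.
#' @return a complete, validated `flow_split`.
#' @export
complete_split <- function(split) {
  miss <- which(is.na(split$fraction))
  if (length(miss) != 1L) {
    stop("exactly one outlet must have an unresolved fraction")
  }
  rest <- expanded_total(split)
  remainder <- 100 - rest
  mult <- if (split$bilateral[miss]) 2 else 1
  if (remainder <= 0) {
    stop(sprintf("over-allocated split: the resolved outlets already total %.4f%%", rest))
  }
  split$fraction[miss] <- remainder / mult
  flow_split(split)
}

#' Per-outlet flows for a given inlet flow
#'
#' Expands bilateral entries into left/right outlets and assigns each
#' physical outlet `fraction/100 * Q`. The outputs sum to `Q` exactly (to
#' rounding).
#'
#' @param split a complete [flow_split()].
#' @param inlet_flow inlet flow Q (any consistent unit).
#' @return tibble with columns `outlet`, `fraction`, `flow`.
#' @export
outlet_flows <- function(split, inlet_flow) {
  if (anyNA(split$fraction)) stop("split is incomplete")
  rows <- purrr::pmap_dfr(split, function(outlet, fraction, bilateral, ...) {
    if (bilateral) {
      tibble::tibble(outlet = paste(outlet, c("left", "right"), sep = "_"),
                     fraction = fraction)
    } else {
      tibble::tibble(outlet = outlet, fraction = fraction)
    }
  })
  rows$flow <- rows$fraction / 100 * inlet_flow
  rows
}

#' Reference outlet split of the multi-outlet aortic model
#'
#' Per-vessel outflow percentages of the collateral-fed descending-aorta
#' model: bilateral carotid 6.48%, bilateral subclavian 18.15%, bilateral
#' mammary 8.73%, descending aorta 33.28% (bilateral entries count twice,
#' closing the balance at 100%).
#'
#' @return a complete [flow_split()].
#' @export
iaa_flow_split <- function() {
  flow_split(tibble::tibble(
    outlet = c("carotid", "subclavian", "mammary", "descending_aorta"),
    fraction = c(6.48, 18.15, 8.73, 33.28),
    bilateral = c(TRUE, TRUE, TRUE, FALSE)
  ))
}

#' Read a flow split from YAML/JSON
#'
#' Expected: a list of `{outlet, fraction, bilateral}` entries (fraction may
#' be null for the one unresolved outlet).
#' @param path file path.
#' @return a `flow_split` (not yet completed if a fraction is missing).
#' @export
read_flow_split <- function(path) {
  spec <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else yaml::read_yaml(path)
  out <- purrr::map_dfr(spec, function(e) {
    tibble::tibble(outlet = e$outlet,
                   fraction = if (is.null(e$fraction)) NA_real_ else as.numeric(e$fraction),
                   bilateral = isTRUE(e$bilateral))
  })
  flow_split(out, check = !anyNA(out$fraction))
}
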