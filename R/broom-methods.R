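#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ordination
#'
#' `tidy()` returns per-axis summaries (for PCA, every eigenvalue and the
#' variance proportions with a `retained` flag; for NMDS, the two axes and
#' their coordinate ranges); `glance()` a one-row model summary.
#'
#' @param x An `ed_ordination`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ed_ordination <- function(x, ...) {
  if (x$kind == "pca") {
    eig <- x$eigenvalues
    tibble::tibble(axis = paste0("PC", seq_along(eig)),
                   eigenvalue = eig,
                   prop_variance = eig / sum(eig),
                   retained = seq_along(eig) <= x$k)
  } else {
    m <- ord_coords(x)
    tibble::tibble(axis = colnames(m),
                   min = apply(m, 2, min),
                   max = apply(m, 2, max))
  }
}

#' @rdname tidy.ed_ordination
#' @export
glance.ed_ordination <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_sites = nrow(x$coordinates),
                 k = x$k,
                 stress = if (x$kind == "nmds2d") x$stress else NA_real_,
                 kaiser_fallback = isTRUE(x$kaiser_fallback))
}

#' Tidy a selection result
#'
#' `tidy()` returns the per-step selection records; `glance()` the method,
#' set size and final objective.
#'
#' @param x An `ed_selection`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ed_selection <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.ed_selection
#' @export
glance.ed_selection <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 m = length(attr(x, "selected")),
                 objective = attr(x, "objective"))
}

#' Summarise an SAI sweep report
#'
#' One row: the median SAI over defined fractions, the fraction count, and
#' how many fractions were defined.
#'
#' @param x An `ed_sai_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ed_sai_report <- function(x, ...) {
  tibble::tibble(median_sai = attr(x, "median_sai"),
                 n_fractions = nrow(x),
                 n_defined = sum(x$defined),
                 optimum_method = attr(x, "optimum_method"),
                 approach = attr(x, "approach") %||% NA_character_,
                 cvt = attr(x, "cvt") %||% NA_character_)
}
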