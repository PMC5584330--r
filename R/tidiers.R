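#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a wiki site into its fact table
#'
#' One row per stored fact, joined with each page's namespace and
#' equivalent URI so the table is self-describing.
#'
#' @param x a `wiki_site`.
#' @param ... unused.
#' @return A tibble with columns `page`, `ns`, `equivalent_uri`,
#'   `property`, `value_kind`, `value`, `datatype`, `language`.
#' @method tidy wiki_site
#' @export
tidy.wiki_site <- function(x, ...) {
  dplyr::left_join(
    x$facts,
    dplyr::select(x$pages, page = "title", "ns", "equivalent_uri"),
    by = "page")
}

#' One-row summary of a wiki site
#'
#' @param x a `wiki_site`.
#' @param ... unused.
#' @return A one-row tibble: page counts per namespace, fact count,
#'   number of typed properties, number of synthesized templates, and
#'   registered URI/title pairs.
#' @method glance wiki_site
#' @export
glance.wiki_site <- function(x, ...) {
  tibble::tibble(
    n_pages = nrow(x$pages),
    n_main = sum(x$pages$ns == "Main"),
    n_properties = sum(x$pages$ns == "Property"),
    n_templates = sum(x$pages$ns == "Template"),
    n_facts = nrow(x$facts),
    n_typed_properties = sum(!is.na(x$pages$smw_type)),
    n_indexed_uris = index_size(x$index)
  )
}

#' Overview plot of a wiki site
#'
#' Bar chart of the number of facts carried per page, split by
#' namespace -- a quick view of how the imported graph spread over the
#' page structure (e.g. association-heavy graphs show many small
#' pages; wide subjects show up as heavy tails).
#'
#' @param object a `wiki_site`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot wiki_site
#' @export
autoplot.wiki_site <- function(object, ...) {
  counts <- dplyr::count(object$facts, .data$page, name = "n_facts")
  df <- dplyr::left_join(
    dplyr::select(object$pages, page = "title", "ns"),
    counts, by = "page")
  df$n_facts[is.na(df$n_facts)] <- 0L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_facts)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~ns, scales = "free_y") +
    ggplot2::labs(x = "facts per page", y = "pages",
                  title = "Fact load per wiki page")
}
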