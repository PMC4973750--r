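#' The 15-class temporal scheme for breeding years
#'
#' Garden-rose collections spanning the "long 19th century" are conventionally
#' stratified into 15 breeding-year bins: everything before 1700, the 18th
#' century, eleven decades from 1800 to 1909, the 1910--1914 pre-war window,
#' and everything after 1914. The scheme partitions all integers, so every
#' known breeding year maps to exactly one class.
#'
#' @return A tibble with columns `label`, `from`, `to` (inclusive bounds;
#'   `-Inf`/`Inf` for the open ends), ordered chronologically.
#' @export
#' @examples
#' temporal_classes()
temporal_classes <- function() {
  decades <- sprintf("%d–%d", seq(1800, 1900, by = 10), seq(1809, 1909, by = 10))
  tibble(
    label = c("<1700", "1700–1799", decades, "1910–1914", ">1914"),
    from  = c(-Inf, 1700, seq(1800, 1900, by = 10), 1910, 1915),
    to    = c(1699, 1799, seq(1809, 1909, by = 10), 1914, Inf)
  )
}

#' Assign breeding years to temporal classes
#'
#' @param year Integer vector of breeding years; `NA` for unknown.
#' @param scheme A class scheme as returned by [temporal_classes()].
#' @return A factor with the scheme's labels as levels (chronological order);
#'   unknown years map to `NA`.
#' @export
#' @examples
#' assign_temporal_class(c(1699, 1845, 1912, NA))
assign_temporal_class <- function(year, scheme = temporal_classes()) {
  stopifnot(all(c("label", "from", "to") %in% names(scheme)))
  if (any(duplicated(scheme$label))) abort("temporal class labels must be unique")
  idx <- vapply(year, function(y) {
    if (is.na(y)) return(NA_integer_)
    hit <- which(y >= scheme$from & y <= scheme$to)
    if (length(hit) != 1L)
      abort(sprintf("year %s maps to %d temporal classes; scheme must partition",
                    y, length(hit)))
    hit
  }, integer(1))
  factor(scheme$label[idx], levels = scheme$label)
}
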