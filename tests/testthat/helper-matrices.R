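# small fixture builders shared by the scoring and acceptance tests

# minimal p-item catalog of direct facility indicators for PCA unit tests
make_mini_catalog <- function(p) {
  doms <- rep(fpqual::qoc_domains()$domain, length.out = p)
  out <- tibble::tibble(
    id = sprintf("item%02d", seq_len(p)), label = sprintf("Item %d", seq_len(p)),
    domain = doms, donabedian = "structure", source_level = "facility",
    rule = "direct", source_fields = sprintf("item%02d", seq_len(p))
  )
  fpqual::validate_catalog(out)
  out
}

# wrap a plain 0/1 matrix as an indicator matrix over a catalog
mini_matrix <- function(x, catalog) {
  colnames(x) <- catalog$id
  out <- dplyr::bind_cols(
    tibble::tibble(facility_id = sprintf("F%03d", seq_len(nrow(x))), weight = 1),
    tibble::as_tibble(x))
  class(out) <- c("qoc_matrix", class(out))
  out
}

# two balanced binary items with exact sample correlation (a - b) / (a + b),
# from a symmetric 2x2 cell layout with counts (a, b, b, a)
two_item_matrix <- function(a, b) {
  x <- c(rep(1, a), rep(1, b), rep(0, b), rep(0, a))
  y <- c(rep(1, a), rep(0, b), rep(1, b), rep(0, a))
  cbind(x, y)
}
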