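# Product-keyword lexicon mapping annotation text to the five canonical
# phage gene modules. This keyword mapping stands in for HMM-based viral
# protein annotation; it is deliberately small, editable and transparent.

PHAGE_MODULES <- c("integration_excision", "lysis", "dna_replication",
                   "head_tail", "dna_packaging")

#' Phage product lexicon
#'
#' Keyword-to-module table used to recognise phage genes in annotation
#' products and to assign them to one of the five canonical modules:
#' integration/excision, lysis, DNA replication, head/tail morphogenesis and
#' DNA packaging. The default table ships with the package as an editable
#' TSV.
#'
#' @param path optional path to a custom two-column TSV (`keyword`,
#'   `module`).
#' @return data.frame with columns `keyword` and `module`.
#' @export
phage_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phage_lexicon.tsv",
                        package = "bifidophage", mustWork = TRUE)
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("keyword", "module") %in% names(lex)),
            all(lex$module %in% PHAGE_MODULES))
  lex
}

#' Assign product labels to phage modules
#'
#' Matches each free-text product label against the lexicon keywords
#' (case-insensitive substring match; first matching keyword wins) and
#' returns the module, or `NA` for non-phage products.
#'
#' @param products character vector of product labels.
#' @param lexicon lexicon table from [phage_lexicon()].
#' @return character vector of module names (or `NA`) parallel to
#'   `products`.
#' @export
assign_modules <- function(products, lexicon = phage_lexicon()) {
  out <- rep(NA_character_, length(products))
  low <- tolower(products)
  for (i in seq_len(nrow(lexicon))) {
    hit <- is.na(out) & grepl(tolower(lexicon$keyword[i]), low, fixed = TRUE)
    out[hit] <- lexicon$module[i]
  }
  out
}

is_hypothetical <- function(products) {
  grepl("hypothetical", tolower(products), fixed = TRUE)
}
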