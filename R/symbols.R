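#' Default gene-symbol synonym table
#'
#' Mouse gene symbols drift between annotation releases; the packaged
#' homolog table and downstream correlation tables mix at least one pair of
#' synonyms for the teashirt homolog. The default table maps the older
#' symbol `Sdccag33` to the current `Tshz1`. Lookup is case-insensitive.
#'
#' @return Named character vector: `names()` are alternate symbols,
#'   values are the canonical symbol.
#' @examples
#' default_synonyms()
#' @export
default_synonyms <- function() {
  c(Sdccag33 = "Tshz1")
}

#' Normalize a gene symbol
#'
#' Trims surrounding whitespace and applies a synonym table
#' (case-insensitively). Normalization is idempotent. Casing of
#' non-synonym symbols is preserved as given; cross-symbol case
#' reconciliation ("first-seen casing wins") is handled by
#' [canonicalize_symbols()] which operates on a whole vector.
#'
#' @param x Character vector of raw symbols.
#' @param synonyms Named character vector mapping alternate symbols to
#'   canonical ones; defaults to [default_synonyms()].
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol("  Pax6 ")
#' normalize_symbol("Sdccag33")  # -> "Tshz1"
#' @export
normalize_symbol <- function(x, synonyms = default_synonyms()) {
  if (!is.character(x)) {
    x <- as.character(x)
  }
  out <- trimws(x)
  if (any(!nzchar(out)) || anyNA(out)) {
    stop("empty or missing gene symbol is not allowed", call. = FALSE)
  }
  if (length(synonyms)) {
    hit <- match(tolower(out), tolower(names(synonyms)))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

#' Canonicalize a vector of gene symbols
#'
#' Applies [normalize_symbol()] then reconciles casing across the vector:
#' symbols equal up to case are mapped to the first-seen spelling.
#' Duplicates (after reconciliation) are retained; callers that need
#' uniqueness handle collapsing themselves (see
#' [read_expression_matrix()]).
#'
#' @inheritParams normalize_symbol
#' @return Character vector, same length as `x`.
#' @export
canonicalize_symbols <- function(x, synonyms = default_synonyms()) {
  out <- normalize_symbol(x, synonyms)
  key <- tolower(out)
  first <- !duplicated(key)
  canon <- out[first]
  names(canon) <- key[first]
  unname(canon[key])
}

# Case-insensitive matching key; assumes input already normalized.
symbol_key <- function(x) tolower(x)
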