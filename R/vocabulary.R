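# Controlled vocabulary and unit registry. Every source term is mapped to
# a canonical variable name; every reported unit is converted to that
# variable's canonical unit before a value enters the vertical store.

# Fold a term for matching: lower-case, strip punctuation and whitespace.
fold_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:][:punct:]]+", "", x)
}

#' Load a controlled vocabulary from a YAML file
#'
#' The file defines the canonical variable set (names, long names,
#' canonical units, category, plausibility and egregious-value
#' thresholds), a synonym map from source terminology to canonical names,
#' and a unit registry (symbol, dimension, multiplicative factor to the
#' dimension's reference unit).
#'
#' @param path path to a vocabulary YAML file; defaults to the packaged
#'   vocabulary of 17 water-quality variables plus lake depth.
#' @return a `controlled_vocabulary` object: list with `variables`
#'   (data.frame), `synonyms` (named character, folded keys), `units`
#'   (data.frame).
#' @export
load_vocabulary <- function(path = system.file("extdata", "vocabulary.yaml",
                                               package = "limnopipe")) {
  raw <- yaml::read_yaml(path)
  vars <- do.call(rbind, lapply(raw$variables, function(v)
    data.frame(canonical_name = tolower(v$canonical_name),
               long_name = v$long_name,
               canonical_units = v$canonical_units,
               category = v$category,
               valid_min = as.numeric(v$valid_min),
               valid_max = as.numeric(v$valid_max),
               egregious_max = as.numeric(v$egregious_max),
               stringsAsFactors = FALSE)))
  # case-folding canonicalization: "tp" and "TP" collapse to one entry,
  # but two *different* definitions under one name are a parse error
  dup <- duplicated(vars$canonical_name)
  for (nm in unique(vars$canonical_name[dup])) {
    defs <- unique(vars[vars$canonical_name == nm, , drop = FALSE])
    if (nrow(defs) > 1)
      stop("duplicate canonical name with conflicting definitions: ", nm)
  }
  vars <- vars[!dup, , drop = FALSE]
  bad <- !(vars$valid_min <= vars$valid_max & vars$valid_max <= vars$egregious_max)
  if (any(bad))
    stop("threshold ordering violated (valid_min <= valid_max <= egregious_max) for: ",
         paste(vars$canonical_name[bad], collapse = ", "))
  cats <- c("nutrient", "clarity", "carbon", "chlorophyll", "depth")
  if (!all(vars$category %in% cats))
    stop("unknown variable category: ",
         paste(setdiff(vars$category, cats), collapse = ", "))

  syn_raw <- raw$synonyms
  syn_keys <- fold_term(names(syn_raw))
  syn_vals <- tolower(unlist(syn_raw, use.names = FALSE))
  # a folded synonym bound to two different canonicals is a parse error
  for (k in unique(syn_keys[duplicated(syn_keys)])) {
    tgts <- unique(syn_vals[syn_keys == k])
    if (length(tgts) > 1)
      stop("synonym '", k, "' is bound to multiple canonical names: ",
           paste(tgts, collapse = ", "))
  }
  keep <- !duplicated(syn_keys)
  synonyms <- stats::setNames(syn_vals[keep], syn_keys[keep])
  bad <- !synonyms %in% vars$canonical_name
  if (any(bad))
    stop("synonyms target unknown canonical names: ",
         paste(unique(synonyms[bad]), collapse = ", "))

  units <- do.call(rbind, lapply(raw$units, function(u)
    data.frame(symbol = u$symbol, dimension = u$dimension,
               factor = as.numeric(u$factor), stringsAsFactors = FALSE)))
  if (any(units$factor <= 0)) stop("unit conversion factors must be positive")
  if (anyDuplicated(units$symbol))
    stop("duplicate unit symbols: ",
         paste(unique(units$symbol[duplicated(units$symbol)]), collapse = ", "))

  structure(list(variables = vars, synonyms = synonyms, units = units),
            class = "controlled_vocabulary")
}

#' @export
print.controlled_vocabulary <- function(x, ...) {
  wq <- sum(x$variables$category != "depth")
  cat("<controlled_vocabulary>", wq, "water-quality variables,",
      sum(x$variables$category == "depth"), "depth variables,",
      length(x$synonyms), "synonyms,", nrow(x$units), "units\n")
  invisible(x)
}

# Normalize unicode micro sign so "µg/L" and "ug/L" are the same symbol.
normalize_unit_symbol <- function(u) {
  u <- gsub("µ|μ", "u", u)
  trimws(u)
}

#' Convert a value between registered units
#'
#' Both units must be registered and share a dimension; conversion is
#' multiplicative via the registry factors. Identical unit symbols return
#' the value exactly unchanged.
#'
#' @param value numeric vector.
#' @param from_unit,to_unit unit symbols (micro sign and "u" are
#'   interchangeable).
#' @param registry a `controlled_vocabulary` or its `units` data.frame.
#' @return converted numeric vector.
#' @export
convert_units <- function(value, from_unit, to_unit, registry) {
  units <- if (inherits(registry, "controlled_vocabulary")) registry$units else registry
  from_unit <- normalize_unit_symbol(from_unit)
  to_unit <- normalize_unit_symbol(to_unit)
  if (identical(from_unit, to_unit)) return(value)
  i <- match(from_unit, units$symbol)
  j <- match(to_unit, units$symbol)
  if (is.na(i)) stop("unregistered unit: ", from_unit)
  if (is.na(j)) stop("unregistered unit: ", to_unit)
  if (units$dimension[i] != units$dimension[j])
    stop("incompatible dimensions: ", from_unit, " (", units$dimension[i],
         ") -> ", to_unit, " (", units$dimension[j], ")")
  value * units$factor[i] / units$factor[j]
}

#' Resolve a source variable term to a canonical name
#'
#' Matching is case-insensitive after whitespace/punctuation folding;
#' otherwise the synonym map is consulted. Unresolvable terms return NA.
#'
#' @param term character vector of source terms.
#' @param vocab a `controlled_vocabulary`.
#' @return character vector of canonical names (NA where unresolved).
#' @export
resolve_variable <- function(term, vocab) {
  f <- fold_term(term)
  out <- vocab$variables$canonical_name[match(f, fold_term(vocab$variables$canonical_name))]
  miss <- is.na(out)
  out[miss] <- unname(vocab$synonyms[f[miss]])
  out
}
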