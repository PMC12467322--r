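# locale-independent label ordering, so serialized output is byte-stable
sortLabels <- function(x) sort(unique(as.character(x)), method = "radix")

stopIfMissingCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# set.seed only when the caller asked for reproducibility, restoring the
# caller's RNG stream afterwards so seeded helpers do not perturb each other
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# align a named numeric vector onto a fixed label set, filling zeros
alignTo <- function(v, labels) {
  out <- stats::setNames(numeric(length(labels)), labels)
  keep <- intersect(names(v), labels)
  out[keep] <- v[keep]
  out
}
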