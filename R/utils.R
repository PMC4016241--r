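# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# order scores descending, ties broken by ascending id; returns indices
order_desc_ties_asc <- function(score, id) {
  order(-score, id, method = "radix")
}

stopifnot_gene_ids <- function(ids, what = "gene id") {
  bad <- !nzchar(ids) | grepl("[[:space:]]", ids)
  if (any(bad)) {
    abort(sprintf("invalid %s: %s", what,
                  paste(utils::head(ids[bad], 3), collapse = ", ")))
  }
  invisible(ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
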