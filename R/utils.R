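# internal helpers shared across modules

# classed errors so callers/tests can discriminate failure modes
aba_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "abasubtypes_error"), ...))
}

stopf <- function(class, fmt, ...) aba_error(sprintf(fmt, ...), class)

# derive a reproducible sub-seed; stays well inside 32-bit integer range
derive_seed <- function(seed, offset) {
  s <- (abs(as.double(seed)) %% 2147483647) * 31 + as.double(offset) * 7919
  as.integer(s %% 2147483562) + 1L
}

# full-precision numeric serialization: %.17g round-trips doubles exactly
format_full <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

# write a data frame with exact numeric round-tripping (NA -> empty cell)
write_table_precise <- function(df, path, sep = ",") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- format_full(out[[j]])
    } else if (is.integer(out[[j]]) || is.logical(out[[j]])) {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    } else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  path
}

sep_for_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = ",",
         tsv = "\t",
         stopf("io_error", "unsupported extension '.%s' (use .csv or .tsv): %s",
               ext, path))
}

# run code with a pinned RNG state, restoring the caller's stream afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
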