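# Internal helpers shared across modules.

# Locale-independent sort: node and gene order must be byte-deterministic
# because the serialized edge index depends on it.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Tokens treated as missing on read (case-insensitive, after trimming).
.missing_tokens <- c("", "na", "nan", "null")

# Convert a character vector to numeric, mapping missing tokens and any
# non-numeric cell to NA.
as_missing_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% .missing_tokens] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# Normalize missing tokens in a character vector without numeric coercion.
normalize_missing <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% .missing_tokens] <- NA_character_
  x
}

# Group-by-mean over matrix rows, ignoring NA within each group.
# Groups with no observed value in a cell yield NA there.
group_rows_mean <- function(values, groups) {
  stopifnot(nrow(values) == length(groups))
  ug <- sort_c(unique(groups))
  out <- matrix(NA_real_, nrow = length(ug), ncol = ncol(values),
                dimnames = list(ug, colnames(values)))
  for (g in ug) {
    block <- values[groups == g, , drop = FALSE]
    out[g, ] <- colMeans(block, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

# Group-by-sum over matrix rows; NA treated as absent contribution.
group_rows_sum <- function(values, groups) {
  stopifnot(nrow(values) == length(groups))
  ug <- sort_c(unique(groups))
  out <- matrix(0, nrow = length(ug), ncol = ncol(values),
                dimnames = list(ug, colnames(values)))
  for (g in ug) {
    block <- values[groups == g, , drop = FALSE]
    out[g, ] <- colSums(block, na.rm = TRUE)
  }
  out
}
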