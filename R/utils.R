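# Internal helpers shared across modules.

# Run `code` under a deterministic RNG state derived from `seed` plus a
# small stage offset, restoring the caller's RNG afterwards. Offsets keep
# the generator stages (genome, MeDIP, RNA, pathology, genes) independent
# so regenerating one input does not perturb the others.
with_stage_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
  withr::with_seed(s, code)
}

geometric_mean <- function(x) exp(mean(log(x)))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integer && x != floor(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Resolve a sample -> group mapping against the sample names of a count
# matrix. Accepts a named character vector or a two-column data frame
# (sample, group). Returns a factor aligned to `samples`; with
# `levels = NULL` the levels follow order of appearance.
resolve_groups <- function(groups, samples, levels = NULL) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample)
  }
  if (is.null(names(groups))) {
    if (length(groups) != length(samples)) {
      abort("Unnamed `groups` must have one entry per sample column.")
    }
    names(groups) <- samples
  }
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L) {
    abort(sprintf("No group label for sample(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  g <- as.character(groups[samples])
  if (is.null(levels)) levels <- unique(g)
  bad <- setdiff(unique(g), levels)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown group label(s): %s (expected %s).",
                  paste(bad, collapse = ", "),
                  paste(levels, collapse = "/")))
  }
  factor(g, levels = levels)
}

# Extract the features-by-samples integer matrix from either a
# window_counts object or a plain matrix/data frame of counts.
as_count_matrix <- function(x) {
  if (inherits(x, "window_counts")) return(x$counts)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    return(m)
  }
  abort("Expected a window_counts object, matrix, or data frame of counts.")
}

provenance_header <- function(seed = NULL) {
  c(if (!is.null(seed)) sprintf("#seed=%s", format(seed)),
    sprintf("#version=dmrkit %s", as.character(packageVersion("dmrkit"))))
}

write_tsv_provenance <- function(df, path, seed = NULL) {
  writeLines(provenance_header(seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
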