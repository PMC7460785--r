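`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' generator calls do not perturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Position-wise identity of two strings: matches over min length divided by
# max length, so length differences count as mismatches.
string_identity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0)
  n <- min(na, nb)
  m <- sum(strsplit(substr(a, 1L, n), "")[[1]] == strsplit(substr(b, 1L, n), "")[[1]])
  m / max(na, nb)
}

# Random residue string from an alphabet (expects RNG already seeded).
random_residues <- function(n, alphabet) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Stable TSV writer: fixed column order, no quoting surprises, LF endings.
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

empty_motif_df <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             sequence = character(), cys_gap = integer(), his_gap = integer(),
             core6 = character(), inter_his = character(),
             mtype = character(), subgroup = character(),
             stringsAsFactors = FALSE)
}

empty_ear_df <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             pattern_id = character(), matched = character(),
             stringsAsFactors = FALSE)
}
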