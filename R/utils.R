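#' @importFrom stats rnorm rbinom runif median sd p.adjust pnorm cor.test
#'   oneway.test cmdscale lm coef setNames complete.cases pf
#' @importFrom utils write.table read.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

.datatable.aware <- TRUE

utils::globalVariables(c(".", "cell", "allele", "i.allele", "snv", "i.snv",
                         "pair_id", "n_AB", "n_Ab", "n_aB", "n_ab",
                         "n_total", "pos1", "pos2", "base"))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# go through this so outputs are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; keeps derived
# seeds within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

str_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_str <- function(x) paste(x, collapse = "")

complement_chars <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
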