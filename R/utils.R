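#' @import methods
#' @importFrom stats cor cor.test rnorm runif rbinom sd predict
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @importFrom IRanges CharacterList
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom IRanges CharacterList
#' @useDynLib OGTpred, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Canonical residue order used throughout: alphabetical single-letter codes.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# The single "unknown" symbol all non-standard residues collapse to at load time.
AA_UNKNOWN <- "X"

TEMP_CLASSES <- c("psychrophilic", "mesophilic", "thermophilic", "excluded")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  expr
}

# Structured log line on stderr; every normalisation/drop decision goes through here.
log_msg <- function(...) {
  message("[OGTpred] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
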