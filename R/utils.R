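#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rbinom rgamma runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locate an executable; "" if absent.
find_executable <- function(name) {
  unname(Sys.which(name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
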