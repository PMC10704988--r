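# Internal helpers shared across modules.

#' @importFrom data.table fread fwrite data.table as.data.table setDF :=
#' @importFrom stats median p.adjust phyper rbinom rlnorm rnbinom rnorm rpois
#'   runif t.test cor cor.test
#' @importFrom utils write.table head
NULL

#' Derive a stable per-key sub-seed from a base seed
#'
#' Randomised stages (read redistribution, simulation) draw all randomness
#' from one user-supplied base seed.  Per-gene work uses a sub-seed obtained
#' by hashing the gene identifier, so results do not depend on the order in
#' which genes are processed.
#'
#' @param base_seed Integer base seed.
#' @param key Character scalar (e.g. a gene id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stable_seed <- function(base_seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(base_seed) + h) %% 2147483647)
}

# Derive a stage sub-seed from a base seed, staying inside 32-bit range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Write a data.frame as a headered TSV, optionally preceded by provenance
# comment lines ("# key=value").  Deterministic byte-for-byte given identical
# input (no timestamps).
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), "=", unname(unlist(provenance))), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Read a TSV written by write_tsv ("# " provenance lines skipped).
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

log_msg <- function(...) message("[rbpscan] ", ...)
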