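#' @keywords internal
"_PACKAGE"

# Chromosome vocabulary used throughout: autosomes "1".."22" plus "X".
# "Y" and "MT" are rejected at ingest; all positions are 1-based on a
# single declared genome build per run.
.AUTOSOMES <- as.character(1:22)
.CHROMS <- c(.AUTOSOMES, "X")

.BASES <- c("A", "C", "G", "T")

.CONSEQUENCES <- c("stop_gain", "frameshift", "splice_donor",
                   "splice_acceptor", "missense", "synonymous")

# Reverse complement of fixed-width-3 contexts, vectorised.
revcomp3 <- function(s) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  paste0(comp(substr(s, 3L, 3L)), comp(substr(s, 2L, 2L)), comp(substr(s, 1L, 1L)))
}

revcomp1 <- function(s) chartr("ACGT", "TGCA", s)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_whole <- function(x) is.numeric(x) & is.finite(x) & x == floor(x)
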