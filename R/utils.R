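# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# classed abort so callers can condition on error families
cs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("cytoscreen_", class), "cytoscreen_error")))
}

is_scatter_channel <- function(ch) grepl("^(FSC|SSC)", ch)

# stable seed derivation; keeps results < 2^31 for R's 32-bit integers
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647
}
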