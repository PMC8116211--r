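# Internal helpers shared across modules.

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used for
# provenance stamping of configurations and input files; not cryptographic.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

hashConfig <- function(x) {
  fnv1a(paste(names(unlist(x)), unlist(x), sep = "=", collapse = ";"))
}

# Deterministic child seed derived from a user seed; kept below 2^31.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# chromosome id per bin as plain character
binChrom <- function(map) as.character(seqnames(binRanges(map)))

# Balanced layer if present, else raw counts. Synthetic Poisson maps carry
# no technical coverage bias, so O/E analytics are valid on raw counts;
# balancing is applied when the user has run balanceICE().
balancedOrCounts <- function(map) {
  b <- balancedCounts(map)
  if (is.null(b)) contactCounts(map) else b
}
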