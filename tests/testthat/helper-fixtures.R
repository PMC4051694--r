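# Shared fixtures and independent brute-force oracles.

# Gaussian elution peak on n scans, unit spacing.
gaussian_trace <- function(n = 7L, area = 100, width = 1.5) {
  rt <- seq_len(n) - 1
  centre <- rt[ceiling(n / 2)]
  list(rt = rt, intensity = area * dnorm(rt, centre, width))
}

# Brute-force tryptic digestion: test every substring for valid tryptic
# termini and count internal missed cleavages. Independent of digest()'s
# fragment-concatenation algorithm.
digest_oracle <- function(sequence, max_missed) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  is_cut <- function(i) { # cleavage between i and i+1
    i >= 1 && i < n && aa[i] %in% c("K", "R") && aa[i + 1] != "P"
  }
  peps <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1 || is_cut(i - 1)
      right_ok <- j == n || is_cut(j)
      if (!left_ok || !right_ok) next
      internal <- if (j > i) sum(vapply((i):(j - 1), is_cut, logical(1))) else 0
      if (internal <= max_missed) peps <- c(peps, substr(sequence, i, j))
    }
  }
  sort(unique(peps))
}

# Brute-force Venn region counts: one membership string per id.
venn_oracle <- function(inventories) {
  methods <- names(inventories)
  ids <- unique(unlist(inventories))
  pattern <- vapply(ids, function(id) {
    paste(methods[vapply(inventories, function(s) id %in% s, logical(1))],
      collapse = "&"
    )
  }, character(1))
  table(pattern)
}

# Random protein sequence with realistic K/R content.
random_protein <- function(len) {
  paste(sample(c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  ), len, replace = TRUE, prob = c(
    8, 1, 5, 6, 4, 7, 2, 6, 6, 10, 2, 4, 5, 4, 6, 6, 5, 7, 1, 3
  )), collapse = "")
}
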