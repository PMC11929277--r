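# Independent full-DP edit-distance oracle (row-rolling Wagner-Fischer),
# kept free of any package code so it can cross-check levenshtein().
lev_dp <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(sa)
  n <- length(sb)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  cur <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur[1] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (sa[i] != sb[j]))
    }
    prev <- cur
  }
  prev[n + 1L]
}

rand_string <- function(alphabet, max_len = 30L, min_len = 0L) {
  paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

mixed_alphabet <- function() {
  c(letters[1:8], LETTERS[1:3], 0:9, " ", "-", ",", ".", "(", ")", "=", "–")
}
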