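# shared fixtures: a small (0.1-scale) locus configuration keeps sequence
# tests fast; all structural targets (1504, 410, 111 bp) are scale-invariant
small_params <- function(seed = 42L, ...) {
  locus_params(scale = 0.1, seed = seed, ...)
}

gy14 <- function() build_line_structure("gynoecious_Gy14_like")
line9930 <- function() build_line_structure("monecious_9930_like")
am297 <- function() build_line_structure("triple_AM297_like")

# independent brute-force gamete enumeration: every (i, j) register pair with
# the concatenation rule applied literally; used as the oracle for
# enumerate_gametes()
brute_gametes <- function(g, mu, max_offset = 1L) {
  u1 <- g$hap1$units; u2 <- g$hap2$units
  res <- list()
  add <- function(units, pr) {
    key <- paste(units, collapse = "")
    res[[key]] <<- (res[[key]] %||% 0) + pr
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  pairs <- expand.grid(i = seq_along(u1), j = seq_along(u2))
  pairs <- pairs[abs(pairs$i - pairs$j) >= 1 &
                 abs(pairs$i - pairs$j) <= max_offset, ]
  if (nrow(pairs) == 0 || mu == 0) {
    add(u1, 0.5); add(u2, 0.5)
  } else {
    add(u1, (1 - mu) / 2); add(u2, (1 - mu) / 2)
    offs <- table(abs(pairs$i - pairs$j))
    w <- rep(1 / max_offset, max_offset)
    w_feas <- w[as.integer(names(offs))]
    w_feas <- w_feas / sum(w_feas)
    for (r in seq_len(nrow(pairs))) {
      d <- abs(pairs$i[r] - pairs$j[r])
      pr <- mu * w_feas[match(d, as.integer(names(offs)))] /
        offs[[as.character(d)]]
      i <- pairs$i[r]; j <- pairs$j[r]
      rec1 <- c(u1[1:i], if (j < length(u2)) u2[(j + 1):length(u2)])
      rec2 <- c(u2[1:j], if (i < length(u1)) u1[(i + 1):length(u1)])
      add(rec1, pr / 2); add(rec2, pr / 2)
    }
  }
  out <- data.frame(haplotype = names(res), prob = unlist(res),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

gamete_prob <- function(dist, key) {
  p <- dist$prob[dist$haplotype == key]
  if (length(p) == 0) 0 else p
}
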