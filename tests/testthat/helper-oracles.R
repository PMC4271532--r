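# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: translation goes through Biostrings, the Fisher
# oracle enumerates the hypergeometric mass directly, and the NG86 oracle
# re-derives site and pathway counts from Biostrings' genetic code.

oracle_translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# exact Fisher p-value for [[a, b], [c, d]] by direct enumeration of the
# hypergeometric distribution over the fixed margins
oracle_fisher <- function(a, b, c, d, sided = "two") {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  if (sided == "two") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else if (sided == "greater") {
    sum(probs[xs >= a])
  } else {
    sum(probs[xs <= a])
  }
}

# all permutations of a vector (n <= 3 in practice)
oracle_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  do.call(c, lapply(seq_along(x), function(i) {
    lapply(oracle_perms(x[-i]), function(r) c(x[i], r))
  }))
}

GC <- Biostrings::GENETIC_CODE

# synonymous site count of a codon: share of the nine single-base mutants
# preserving the amino acid (mutation to stop counts as nonsynonymous)
oracle_ng86_sites <- function(codon) {
  b <- strsplit(codon, "")[[1L]]
  hits <- 0
  for (pos in 1:3) {
    for (nb in setdiff(c("A", "C", "G", "T"), b[pos])) {
      mb <- b
      mb[pos] <- nb
      mut <- paste(mb, collapse = "")
      if (GC[[mut]] != "*" && GC[[mut]] == GC[[codon]]) hits <- hits + 1
    }
  }
  hits / 3
}

# pathway-averaged (syn, nonsyn) difference counts between two codons,
# excluding pathways through stop codons (fall back to all pathways when
# every route is blocked)
oracle_ng86_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  pos <- which(b1 != b2)
  if (!length(pos)) return(c(0, 0))
  walk <- function(order, allow_stop) {
    cur <- b1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b2[p]
      if (!allow_stop && GC[[paste(nxt, collapse = "")]] == "*") {
        return(NULL)
      }
      if (GC[[paste(nxt, collapse = "")]] ==
          GC[[paste(cur, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- oracle_perms(pos)
  res <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}
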