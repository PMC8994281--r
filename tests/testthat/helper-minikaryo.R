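# Shared fixtures and independent oracles for the test suite.

# Exhaustive-enumeration alignment oracle: recursively enumerates every
# global alignment of two short sequences under affine gap costs
# (a gap of length L costs open + L * extend) and returns the best score.
# Independent of the package's DP implementation.
oracle_align_score <- function(a, b, sub, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, "M", sc + sub[A[i], B[j]])
    }
    if (i <= length(A)) rec(i + 1, j, "X", sc - if (prev == "X") ge else go + ge)
    if (j <= length(B)) rec(i, j + 1, "Y", sc - if (prev == "Y") ge else go + ge)
  }
  rec(1, 1, "", 0)
  best
}

rand_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# point-mutate a sequence: each site changed to a DIFFERENT base with
# probability p (used where tests need guaranteed mismatches)
mutate_seq <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

seal_fixtures <- function() seal_louse_karyotypes()

quartet_tree <- function() {
  ape::read.tree(text = "((t1:0.1,t2:0.1)n2:0.1,(t3:0.1,t4:0.1)n3:0.1)n1;")
}
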