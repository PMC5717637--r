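# Independent Nei-Gojobori oracles: classify each single-nucleotide change
# against the code table directly; average pathway counts by explicit
# enumeration of orderings.

oracle_sites <- function(codon, code = invertMitoCode()) {
  nt <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (alt in setdiff(nt, ch[pos])) {
    mut <- ch; mut[pos] <- alt
    if (code[[paste(mut, collapse = "")]] == code[[codon]]) syn <- syn + 1
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

oracle_diffs <- function(c1, c2, code = invertMitoCode()) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  perms <- if (length(dp) == 1) matrix(dp, 1) else {
    pr <- NULL
    gen <- function(v, acc) {
      if (!length(v)) { pr <<- rbind(pr, acc); return(invisible()) }
      for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
    gen(dp, integer()); pr
  }
  walk <- function(ord, allowStops) {
    cur <- a; sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (!allowStops && (aa1 == "*" || aa2 == "*")) return(NULL)
      if (aa1 != "*" && aa2 != "*" && aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(asplit(perms, 1), walk, allowStops = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    res <- lapply(asplit(perms, 1), walk, allowStops = TRUE)
  m <- Reduce(`+`, res) / length(res)
  c(sd = m[1], nd = m[2])
}

random_codon <- function(code) {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    if (code[[cd]] != "*") return(cd)
  }
}

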