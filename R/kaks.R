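#' Synonymous/nonsynonymous site counts for one codon
#'
#' Nei-Gojobori style site counting: each codon position contributes
#' (number of the 3 possible single-nucleotide changes at that position
#' that preserve the amino acid) / 3 synonymous sites; changes to stop
#' codons count as nonsynonymous.  s + n = 3 exactly.
#'
#' @param codon 3-letter string over A, C, G, T.
#' @param code named character vector mapping codons to amino acids, as
#'   returned by \code{Biostrings::getGeneticCode}; defaults to the
#'   invertebrate mitochondrial code (translation table 5).
#' @return numeric c(s, n).
#' @examples
#' countSites("GGA")  # third position wholly synonymous: s = 1, n = 2
#' @export
countSites <- function(codon, code = invertMitoCode()) {
  codon <- toupper(codon)
  .checkCodon(codon)
  aa <- code[[codon]]
  if (aa == "*") stop("stop codon ", codon, " in coding sequence")
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nt, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      if (code[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

#' Synonymous/nonsynonymous difference counts between two codons
#'
#' For codons differing at m positions, the synonymous and nonsynonymous
#' change counts are averaged over all m! orderings of single-step mutation
#' pathways.  Pathways passing through a stop codon are excluded; if every
#' pathway is blocked by stops, all pathways are used with steps into or
#' out of a stop codon counted as nonsynonymous (the fallback convention
#' of NG86-style implementations).  Always sd + nd = m.
#'
#' @param c1,c2 codon strings.
#' @param code genetic code vector (see \code{\link{countSites}}).
#' @return numeric c(sd, nd).
#' @export
countDifferences <- function(c1, c2, code = invertMitoCode()) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  .checkCodon(c1); .checkCodon(c2)
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffpos <- which(a != b)
  m <- length(diffpos)
  if (m == 0L) return(c(sd = 0, nd = 0))
  paths <- .permutations(diffpos)
  tally <- function(skipStops) {
    tot <- c(0, 0); used <- 0L
    for (p in seq_len(nrow(paths))) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in paths[p, ]) {
        nxt <- cur
        nxt[pos] <- b[pos]
        aa1 <- code[[paste(cur, collapse = "")]]
        aa2 <- code[[paste(nxt, collapse = "")]]
        if (skipStops && (aa1 == "*" || aa2 == "*")) { blocked <- TRUE; break }
        if (aa1 != "*" && aa2 != "*" && aa1 == aa2) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) { tot <- tot + c(sd, nd); used <- used + 1L }
    }
    list(tot = tot, used = used)
  }
  res <- tally(skipStops = TRUE)
  if (res$used == 0L) res <- tally(skipStops = FALSE)
  c(sd = res$tot[1] / res$used, nd = res$tot[2] / res$used)
}

.permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], .permutations(v[-i])))
  out
}

.checkCodon <- function(codon) {
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon))
    stop("invalid codon: ", codon)
}

#' Invertebrate mitochondrial genetic code
#'
#' @return Named character vector (codon -> amino acid, "*" = stop) for
#'   translation table 5, the code of insect mitochondria.
#' @export
invertMitoCode <- function() {
  Biostrings::getGeneticCode("5")
}

#' Ka/Ks ratio between two in-frame coding sequences
#'
#' Approximate (counting) method: Nei-Gojobori site and pathway counting
#' with Jukes-Cantor correction.  Site counts are averaged over the two
#' sequences; ps = Sd/S, pn = Nd/N; Ks = -(3/4) log(1 - (4/3) ps) and Ka
#' likewise; ratio = Ka/Ks.  Codons containing a gap or N in either
#' sequence are dropped pairwise (count reported).  Purifying selection is
#' indicated by a ratio well below 1, neutrality by ~1, positive selection
#' by > 1.
#'
#' @param seq1,seq2 equal-length in-frame nucleotide strings (or a
#'   2-record \code{DNAStringSet}), length divisible by 3.
#' @param code genetic code (default invertebrate mitochondrial).
#' @return list with S, N, Sd, Nd, ps, pn, Ka, Ks, ratio,
#'   \code{ratio_defined} (FALSE when Ks = 0) and \code{dropped_codons}.
#' @export
kaksRatio <- function(seq1, seq2 = NULL, code = invertMitoCode()) {
  if (is.null(seq2)) {
    if (length(seq1) != 2L) stop("need exactly two sequences")
    seq2 <- as.character(seq1[[2]]); seq1 <- as.character(seq1[[1]])
  }
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)")
  if (nchar(seq1) %% 3 != 0) stop("length must be divisible by 3 (in frame)")
  ncod <- nchar(seq1) / 3
  if (ncod < 1) stop("need at least one codon")
  S1 <- S2 <- Sd <- Nd <- 0
  dropped <- 0L
  for (i in seq_len(ncod)) {
    c1 <- substr(seq1, 3 * i - 2, 3 * i)
    c2 <- substr(seq2, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) {
      dropped <- dropped + 1L
      next
    }
    if (code[[c1]] == "*" || code[[c2]] == "*")
      stop("internal stop codon at codon ", i)
    s1 <- countSites(c1, code); s2 <- countSites(c2, code)
    S1 <- S1 + s1[["s"]]; S2 <- S2 + s2[["s"]]
    dd <- countDifferences(c1, c2, code)
    Sd <- Sd + dd[["sd"]]; Nd <- Nd + dd[["nd"]]
  }
  used <- ncod - dropped
  if (used < 1) stop("no comparable codons")
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  if (ps >= 3 / 4 || pn >= 3 / 4)
    stop("saturation error: proportion of differences >= 3/4, ",
         "Jukes-Cantor correction undefined")
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  defined <- Ks > 0
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ka = Ka, Ks = Ks,
       ratio = if (defined) Ka / Ks else NA_real_,
       ratio_defined = defined, dropped_codons = dropped)
}
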