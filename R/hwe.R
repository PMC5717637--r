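#' Genotype counts for one locus
#'
#' @param gt \code{GenotypeTable}.
#' @param locus locus name.
#' @return list with \code{alleles} (sorted labels), \code{counts}
#'   (symmetric matrix of genotype counts, upper triangle + diagonal
#'   populated), \code{alleleCounts} and \code{n} (genotyped individuals;
#'   missing individuals are excluded for this locus only).
#' @export
locusCounts <- function(gt, locus) {
  if (!(locus %in% gt@loci)) stop("unknown locus: ", locus)
  cell <- genotypeCalls(gt)[, locus]
  cell <- cell[!is.na(cell)]
  parts <- strsplit(cell, "/", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  alleles <- sort(unique(c(a, b)))
  k <- length(alleles)
  cnt <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_along(a)) {
    ii <- match(a[i], alleles); jj <- match(b[i], alleles)
    cnt[min(ii, jj), max(ii, jj)] <- cnt[min(ii, jj), max(ii, jj)] + 1L
  }
  ac <- setNames(2L * diag(cnt) + (rowSums(cnt) - diag(cnt)) +
                   (colSums(cnt) - diag(cnt)), alleles)
  list(alleles = alleles, counts = cnt, alleleCounts = as.integer(ac) |>
         setNames(alleles),
       n = length(cell))
}

.leveneLogProb <- function(counts) {
  # log Pr(table | allele counts) under Levene's conditional distribution;
  # counts uses upper-triangular (incl. diagonal) storage
  up <- counts
  up[lower.tri(up)] <- 0L
  n <- sum(up)
  H <- n - sum(diag(up))
  ac <- 2L * diag(up) + (rowSums(up) - diag(up)) + (colSums(up) - diag(up))
  lfactorial(n) + sum(lfactorial(ac)) + H * log(2) -
    lfactorial(2 * n) - sum(lfactorial(up[upper.tri(up, diag = TRUE)]))
}

# enumerate all genotype tables with the given allele counts; calls f(tab)
.enumTables <- function(alleleCounts, f, cap = 2e6) {
  k <- length(alleleCounts)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  nvisit <- 0L
  tab <- matrix(0L, k, k)
  rec <- function(ci, rem) {
    if (nvisit > cap) stop("enumeration too large; use mc mode")
    if (ci > nrow(cells)) {
      if (all(rem == 0L)) {
        nvisit <<- nvisit + 1L
        f(tab)
      }
      return(invisible())
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    maxc <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (cnt in 0:maxc) {
      tab[i, j] <<- cnt
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * cnt
      else { rem2[i] <- rem2[i] - cnt; rem2[j] <- rem2[j] - cnt }
      # prune: an allele whose remaining copies cannot be placed later
      later <- cells[-seq_len(ci), , drop = FALSE]
      ok <- TRUE
      for (al in seq_len(k)) {
        if (rem2[al] > 0L && !any(later[, 1] == al | later[, 2] == al)) {
          ok <- FALSE; break
        }
      }
      if (ok) rec(ci + 1L, rem2)
    }
    tab[i, j] <<- 0L
  }
  rec(1L, as.integer(alleleCounts))
  invisible(nvisit)
}

#' Exact Hardy-Weinberg test for one locus
#'
#' Probability test: the p-value is the total conditional probability
#' (Levene's distribution, conditioning on the allele counts) of all
#' genotype tables no more probable than the observed one.  The one-sided
#' deficit and excess tests use the total heterozygote count as score
#' statistic.  \code{mode = "enumerate"} enumerates every table;
#' \code{mode = "mc"} runs a Guo-Thompson style switching chain with the
#' given (dememorization, batches, iterations per batch) and reports the
#' batch-based standard error.  \code{"auto"} enumerates when feasible
#' (few alleles, small sample).
#'
#' @param lc locus counts from \code{\link{locusCounts}} (or a
#'   \code{GenotypeTable} plus \code{locus}).
#' @param locus locus name when \code{lc} is a \code{GenotypeTable}.
#' @param mode "auto", "enumerate" or "mc".
#' @param chain numeric length-3 Markov chain parameters
#'   (dememorization, batches, iterations per batch).
#' @return list with \code{p_prob}, \code{p_deficit}, \code{p_excess},
#'   standard errors (NA for enumeration), \code{method}, \code{flag}
#'   ("ok" or "monomorphic: test undefined") and \code{H_obs}.
#' @export
hweExact <- function(lc, locus = NULL, mode = c("auto", "enumerate", "mc"),
                     chain = c(10000, 100, 10000)) {
  mode <- match.arg(mode)
  if (is(lc, "GenotypeTable")) lc <- locusCounts(lc, locus)
  k <- length(lc$alleles)
  if (lc$n < 2) stop("need at least 2 genotyped individuals")
  if (k < 2)
    return(list(p_prob = 1, p_deficit = 1, p_excess = 1,
                se_prob = NA_real_, se_deficit = NA_real_,
                se_excess = NA_real_, method = "none",
                flag = "monomorphic: test undefined",
                H_obs = 0L))
  if (mode == "auto")
    mode <- if (k <= 3 && lc$n <= 100 || k == 2) "enumerate" else "mc"
  H_obs <- sum(lc$counts) - sum(diag(lc$counts))
  if (mode == "enumerate") {
    lp_obs <- .leveneLogProb(lc$counts)
    tot <- 0; p <- 0; pd <- 0; pe <- 0
    .enumTables(lc$alleleCounts, function(tab) {
      lp <- .leveneLogProb(tab)
      pr <- exp(lp)
      tot <<- tot + pr
      if (lp <= lp_obs + 1e-9) p <<- p + pr
      H <- sum(tab) - sum(diag(tab))
      if (H <= H_obs) pd <<- pd + pr
      if (H >= H_obs) pe <<- pe + pr
    })
    # tot == 1 up to numerical error; normalise defensively
    list(p_prob = p / tot, p_deficit = pd / tot, p_excess = pe / tot,
         se_prob = NA_real_, se_deficit = NA_real_, se_excess = NA_real_,
         method = "enumerate", flag = "ok", H_obs = H_obs,
         total_prob = tot)
  } else {
    res <- .gt_chain_cpp(lc$counts, as.integer(chain[1]),
                         as.integer(chain[2]), as.integer(chain[3]),
                         FALSE)
    bse <- function(x) sd(x) / sqrt(length(x))
    list(p_prob = mean(res$prob), p_deficit = mean(res$deficit),
         p_excess = mean(res$excess),
         se_prob = bse(res$prob), se_deficit = bse(res$deficit),
         se_excess = bse(res$excess),
         method = "mc", flag = "ok", H_obs = H_obs,
         accept_rate = res$accept_rate)
  }
}

#' Hardy-Weinberg tests across all loci of a table
#'
#' @param gt \code{GenotypeTable}.
#' @param mode,chain see \code{\link{hweExact}}.
#' @return data.frame, one row per locus, with allele count, n, the three
#'   p-values, standard errors and flags.
#' @export
hweTable <- function(gt, mode = "auto", chain = c(10000, 100, 10000)) {
  rows <- lapply(gt@loci, function(l) {
    lc <- locusCounts(gt, l)
    r <- hweExact(lc, mode = mode, chain = chain)
    data.frame(locus = l, n_alleles = length(lc$alleles), n = lc$n,
               p_prob = r$p_prob, p_deficit = r$p_deficit,
               p_excess = r$p_excess, se_prob = r$se_prob,
               se_deficit = r$se_deficit, se_excess = r$se_excess,
               method = r$method, flag = r$flag)
  })
  do.call(rbind, rows)
}

#' Multilocus exact Hardy-Weinberg test
#'
#' Global one-sided test across loci: the score statistic is the summed
#' per-locus heterozygote count; its null distribution is obtained by
#' joint Markov chain resampling (independent switching chains per locus,
#' statistic summed per iteration).  The global p-value is the tail
#' probability of the observed sum in the resampled distribution (with
#' ties included), with a batch-based standard error.
#'
#' @param gt \code{GenotypeTable}.
#' @param direction "deficit" (global heterozygote deficit) or "excess".
#' @param chain Markov chain parameters (dememorization, batches,
#'   iterations per batch), shared across loci.
#' @return list with \code{p}, \code{se}, \code{direction},
#'   \code{loci_used}.
#' @export
multilocusHWE <- function(gt, direction = c("deficit", "excess"),
                          chain = c(10000, 100, 10000)) {
  direction <- match.arg(direction)
  traces <- list(); Hobs <- 0L
  for (l in gt@loci) {
    lc <- locusCounts(gt, l)
    if (length(lc$alleles) < 2) next
    res <- .gt_chain_cpp(lc$counts, as.integer(chain[1]),
                         as.integer(chain[2]), as.integer(chain[3]), TRUE)
    traces[[l]] <- res$H_trace
    Hobs <- Hobs + (sum(lc$counts) - sum(diag(lc$counts)))
  }
  if (length(traces) == 0L) stop("zero testable (polymorphic) loci")
  Hsum <- Reduce(`+`, traces)
  ind <- if (direction == "deficit") Hsum <= Hobs else Hsum >= Hobs
  nb <- as.integer(chain[2])
  batch <- colMeans(matrix(ind, ncol = nb))
  list(p = mean(ind), se = sd(batch) / sqrt(nb), direction = direction,
       loci_used = names(traces), H_obs = Hobs)
}
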