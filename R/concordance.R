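#' Encode genotypes and traits as a numeric matrix
#'
#' Each observed allele at each locus becomes one column holding the
#' allele dosage: 0 (absent), 1 (heterozygous) or 2 (homozygous), so the
#' dosage columns of a locus sum to 2 for a fully genotyped sample.
#' Trait columns are appended unchanged, one column per trait.  Missing
#' genotypes are imputed with the locus-wise mean dosage (flagged in the
#' result) so that downstream PCA stays defined.
#'
#' @param gt \code{GenotypeTable}.
#' @param traits data.frame of numeric traits, rownames = sample ids
#'   (optional).
#' @return numeric matrix (samples x columns) with attributes
#'   \code{"origin"} (locus/trait per column) and \code{"imputed"}
#'   (sample, locus pairs that were mean-imputed).
#' @export
encodeMatrix <- function(gt, traits = NULL) {
  calls <- genotypeCalls(gt)
  if (!is.null(traits)) {
    missing <- setdiff(gt@samples, rownames(traits))
    extra <- setdiff(rownames(traits), gt@samples)
    if (length(missing) || length(extra))
      stop("sample sets differ between genotypes and traits: ",
           paste(c(missing, extra), collapse = ", "))
    traits <- traits[gt@samples, , drop = FALSE]
  }
  cols <- list(); origin <- character(); imputed <- NULL
  for (l in gt@loci) {
    cell <- calls[, l]
    parts <- strsplit(ifelse(is.na(cell), "NA/NA", cell), "/", fixed = TRUE)
    a1 <- vapply(parts, `[`, "", 1L); a2 <- vapply(parts, `[`, "", 2L)
    alleles <- sort(unique(c(a1[!is.na(cell)], a2[!is.na(cell)])))
    if (length(alleles) == 0L)
      stop("locus ", l, " has no observed alleles")
    dose <- sapply(alleles, function(al)
      (a1 == al) + (a2 == al))
    dose <- matrix(as.numeric(dose), nrow = length(cell))
    miss <- is.na(cell)
    if (any(miss)) {
      mu <- colMeans(dose[!miss, , drop = FALSE])
      dose[miss, ] <- matrix(mu, sum(miss), length(mu), byrow = TRUE)
      imputed <- rbind(imputed,
                       data.frame(sample = gt@samples[miss], locus = l))
    }
    colnames(dose) <- paste(l, alleles, sep = ".")
    cols[[l]] <- dose
    origin <- c(origin, rep(l, length(alleles)))
  }
  m <- do.call(cbind, cols)
  if (!is.null(traits)) {
    m <- cbind(m, as.matrix(traits))
    origin <- c(origin, colnames(traits))
  }
  rownames(m) <- gt@samples
  attr(m, "origin") <- origin
  attr(m, "imputed") <- imputed
  m
}

#' Principal components of the coded matrix
#'
#' Singular value decomposition of the (optionally centred, optionally
#' scaled) matrix via \code{stats::prcomp}.  With \code{centre = FALSE}
#' and \code{scale = TRUE} — the convention used for allele-dosage data
#' here — each column is divided by its root mean square about zero.
#' Zero-RMS columns are an error (named), never silently dropped.
#'
#' @param m numeric matrix from \code{\link{encodeMatrix}}.
#' @param centre,scale logicals passed to \code{prcomp}.
#' @return list with \code{scores} (samples x components),
#'   \code{loadings}, \code{varprop} and \code{cumprop}.
#' @export
pcaScores <- function(m, centre = FALSE, scale = TRUE) {
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (scale) {
    rms <- if (centre) apply(m, 2, sd)
           else sqrt(colSums(m^2) / (nrow(m) - 1))
    bad <- colnames(m)[rms == 0]
    if (length(bad))
      stop("zero-variance column(s) cannot be scaled: ",
           paste(bad, collapse = ", "))
  }
  p <- prcomp(m, center = centre, scale. = scale)
  v <- p$sdev^2
  list(scores = p$x, loadings = p$rotation,
       varprop = v / sum(v), cumprop = cumsum(v) / sum(v))
}

#' Model-based clustering with BIC over a component range
#'
#' Fits Gaussian mixture models over \code{kRange} components and the
#' given covariance parameterisations by EM, selecting the model that
#' maximises BIC = 2 log L - m log n (larger is better).  Components k
#' with n <= k are skipped with a warning; degenerate fits are excluded,
#' not fatal.  Fitting is deterministic (agglomerative initialisation),
#' so results are reproducible.
#'
#' @param scores numeric matrix of component scores (e.g. the first five
#'   PCs).
#' @param kRange integer candidate component counts (default 1:9).
#' @param modelNames covariance families (default: all families available
#'   in \pkg{mclust} for the data).
#' @return list with \code{k}, \code{model}, \code{bic} (the winning
#'   value), \code{classification}, \code{z} (membership probabilities),
#'   \code{bicTable} (full model x k BIC matrix).
#' @export
gmmCluster <- function(scores, kRange = 1:9, modelNames = NULL) {
  n <- nrow(scores)
  drop <- kRange[kRange >= n]
  if (length(drop)) {
    warning("skipping component counts >= n: ",
            paste(drop, collapse = ", "))
    kRange <- kRange[kRange < n]
  }
  if (length(kRange) == 0L) stop("no feasible component count")
  bic <- mclust::mclustBIC(scores, G = kRange, modelNames = modelNames,
                           verbose = FALSE)
  fit <- mclust::Mclust(scores, x = bic, verbose = FALSE)
  if (is.null(fit)) stop("all mixture fits degenerate")
  list(k = fit$G, model = fit$modelName, bic = max(fit$BIC, na.rm = TRUE),
       classification = setNames(fit$classification, rownames(scores)),
       z = fit$z, bicTable = bic)
}

#' Cohen's kappa between two categorical assignments
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with p_o
#' the observed fraction of equal labels and p_e the expected agreement
#' from the marginal label frequencies.  Labels are compared literally;
#' an explicit \code{labelMap} can recode the first assignment (e.g.
#' haplogroup "2" -> cluster "1").  Optional best-match relabelling
#' (\code{match = "best"}) maximises agreement over label bijections —
#' useful when cluster labels are arbitrary, but never the default since
#' silent optimal matching inflates kappa.
#'
#' @param assignA,assignB equal-length vectors of category labels.
#' @param labelMap optional named vector mapping A's labels (injective).
#' @param match "none" (default), "best" (bijective relabelling of A
#'   maximising agreement) or "majority" (each A label mapped to the B
#'   label it most often co-occurs with — the standard way to score a
#'   fine clustering against a coarser reference partition; inflates
#'   agreement when A has many small clusters, so interpret against a
#'   high threshold).
#' @return list with \code{kappa}, \code{p_o}, \code{p_e}, \code{table}.
#' @examples
#' cohensKappa(c(1, 1, 2), c(1, 1, 2))$kappa  # 1
#' @export
cohensKappa <- function(assignA, assignB, labelMap = NULL,
                        match = c("none", "best", "majority")) {
  match <- match.arg(match)
  if (length(assignA) != length(assignB))
    stop("assignment vectors must have equal length")
  a <- as.character(assignA); b <- as.character(assignB)
  if (!is.null(labelMap)) {
    lm <- setNames(as.character(labelMap), names(labelMap))
    if (anyDuplicated(lm)) stop("labelMap must be injective")
    hit <- a %in% names(lm)
    a[hit] <- lm[a[hit]]
  }
  if (match == "majority") {
    tab <- table(a, b)
    mp <- setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
    a <- unname(mp[a])
  } else if (match == "best") {
    la <- unique(a); lb <- unique(b)
    if (length(la) > 6)
      stop("best-match relabelling supported for <= 6 labels")
    best <- -Inf; besta <- a
    fill <- c(lb, setdiff(la, lb))
    perms <- .permutations(seq_len(max(length(la), length(lb))))
    for (p in seq_len(nrow(perms))) {
      mp <- setNames(fill[perms[p, seq_along(la)]], la)
      cand <- mp[a]
      agr <- sum(cand == b)
      if (agr > best) { best <- agr; besta <- cand }
    }
    a <- as.character(besta)
  }
  labs <- union(a, b)
  po <- mean(a == b)
  pa <- table(factor(a, labs)) / length(a)
  pb <- table(factor(b, labs)) / length(b)
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, p_o = po, p_e = pe,
       table = table(A = factor(a, labs), B = factor(b, labs)))
}
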