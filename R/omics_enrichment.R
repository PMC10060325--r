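# Label-free proteome statistics: volcano-style differential-abundance
# filtering, EASE-style modified Fisher enrichment, pathway z-score
# estimation statistics, and the qPCR mtDNA/nDNA copy-number ratio.

#' Read a proteins x samples abundance TSV
#'
#' First column = protein id, remaining columns = samples (linear-scale
#' abundances).
#' @param path TSV path.
#' @return numeric matrix, proteins in rows.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate protein ids in abundance table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write an abundance matrix to TSV
#' @param mat proteins x samples matrix. @param path output path.
#' @export
write_abundance <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read pathway definitions from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name <tab> description <tab> member ids...`.
#' @param path GMT path.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  if (any(!lengths(out))) stop("GMT contains an empty pathway")
  out
}

#' Write pathways to GMT
#' @param pathways named list of member-id vectors. @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Volcano-style differential-abundance filter
#'
#' Per-protein two-sided t-test between two groups on log2-transformed
#' abundances (the field norm for label-free intensities), with the fold
#' change reported on the linear scale as the ratio of group geometric
#' means. A protein is called differential iff `p < alpha` AND the fold
#' change is `>= fold_threshold` or `<= 1/fold_threshold`. Proteins with
#' zero variance in both groups are excluded with a reason code.
#'
#' @param mat proteins x samples abundance matrix (linear scale).
#' @param groups sample -> group labels (length = ncol(mat), 2 levels).
#' @param fold_threshold linear fold-change gate (default 1.5).
#' @param alpha p-value gate (default 0.05, on raw p).
#' @param adjust gate on BH-adjusted q instead of raw p.
#' @param log_transform t-test on log2 scale (default) or declared scale.
#' @param reference reference group (ratio denominator); default first
#'   level.
#' @return object of class `de_result`: list with `table` (per protein:
#'   fold_change, log2_ratio, p, q, direction, excluded reason) and
#'   `summary` (up, down, tested).
#' @export
de_filter <- function(mat, groups, fold_threshold = 1.5, alpha = 0.05,
                      adjust = FALSE, log_transform = TRUE,
                      reference = NULL) {
  if (fold_threshold <= 0) stop("fold_threshold must be positive")
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("de_filter() compares exactly 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  if (is.null(reference)) reference <- levels(groups)[1L]
  other <- setdiff(levels(groups), reference)
  if (nrow(mat) == 0L) {
    return(structure(list(
      table = data.frame(protein_id = character(0), fold_change = numeric(0),
                         log2_ratio = numeric(0), p = numeric(0),
                         q = numeric(0), direction = character(0),
                         significant = logical(0), excluded = character(0)),
      summary = c(up = 0L, down = 0L, tested = 0L)), class = "de_result"))
  }
  x <- if (log_transform) log2(mat) else mat
  ref_idx <- groups == reference
  trt_idx <- groups == other

  res <- t(apply(x, 1L, function(v) {
    a <- v[trt_idx]; b <- v[ref_idx]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(c(diff = mean(a) - mean(b), p = NA_real_))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    c(diff = mean(a) - mean(b), p = tt$p.value)
  }))
  log2_ratio <- if (log_transform) res[, "diff"] else NA_real_
  fc <- if (log_transform) 2^res[, "diff"]
        else {
          rowMeans(mat[, trt_idx, drop = FALSE]) /
            rowMeans(mat[, ref_idx, drop = FALSE])
        }
  p <- res[, "p"]
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  gate_p <- if (adjust) q else p
  fold_pass <- fc >= fold_threshold | fc <= 1 / fold_threshold
  sig <- ok & gate_p < alpha & fold_pass
  direction <- ifelse(!sig, "ns", ifelse(fc > 1, "up", "down"))
  tab <- data.frame(protein_id = rownames(mat),
                    fold_change = unname(fc),
                    log2_ratio = unname(log2_ratio),
                    p = unname(p), q = unname(q),
                    direction = direction,
                    significant = unname(sig),
                    excluded = ifelse(ok, "", "zero variance in both groups"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab,
                 summary = c(up = sum(sig & fc > 1),
                             down = sum(sig & fc < 1),
                             tested = sum(ok))),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  s <- x$summary
  cat("Differential abundance: ", s["tested"], " tested, ",
      s["up"], " up, ", s["down"], " down\n", sep = "")
  invisible(x)
}

#' EASE-style modified Fisher enrichment p-value
#'
#' One-sided over-representation p for an overlap of `k` hits between a
#' differential set of size `n` and a pathway of size `K` in a universe
#' of `N` proteins. The EASE score penalizes small overlaps by
#' subtracting one hit: p = P(X >= max(k - 1, 0)) under the
#' hypergeometric null. `method = "fisher"` gives the unmodified
#' one-sided test; `method = "decrement"` decrements the hit cell of the
#' 2x2 table before a one-sided Fisher test (the other common reading of
#' the same recipe).
#'
#' @param k observed overlap. @param n differential-set size.
#' @param K pathway size (within the universe). @param N universe size.
#' @param method `"ease"` (default), `"fisher"` or `"decrement"`.
#' @return one-sided p-value.
#' @export
ease_fisher <- function(k, n, K, N, method = c("ease", "fisher",
                                               "decrement")) {
  method <- match.arg(method)
  if (k > min(n, K) || n > N || K > N || k < 0)
    stop("inconsistent 2x2 margins: k=", k, " n=", n, " K=", K, " N=", N)
  if (method == "decrement") {
    k2 <- max(k - 1L, 0L)
    tab <- matrix(c(k2, K - k2, n - k2, N - K - (n - k2)), nrow = 2L)
    if (any(tab < 0)) stop("inconsistent 2x2 margins after decrement")
    return(stats::fisher.test(tab, alternative = "greater")$p.value)
  }
  kk <- if (method == "ease") max(k - 1L, 0L) else k
  # P(X >= kk) with X ~ Hypergeometric(K successes, N - K failures, n draws)
  stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Pathway enrichment across a GMT collection with BH FDR
#'
#' @param de_ids character vector of differential protein ids.
#' @param pathways named list from [read_gmt()].
#' @param universe character vector of all quantified protein ids.
#' @param method passed to [ease_fisher()].
#' @return data frame: pathway, pathway size in universe, overlap, p,
#'   BH q; pathways with no member in the universe are reported with
#'   `in_universe = 0` and `p = NA`.
#' @export
enrich_pathways <- function(de_ids, pathways, universe,
                            method = "ease") {
  de_ids <- intersect(unique(de_ids), universe)
  N <- length(unique(universe))
  n <- length(de_ids)
  rows <- lapply(names(pathways), function(nm) {
    mem <- intersect(pathways[[nm]], universe)
    K <- length(mem)
    k <- length(intersect(mem, de_ids))
    p <- if (K == 0L) NA_real_ else ease_fisher(k, n, K, N, method)
    data.frame(pathway = nm, in_universe = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Pathway z-score estimation statistics
#'
#' Each protein's abundances are standardized across *all* samples (the
#' overall experimental mean and SD), so a protein's z-scores have mean 0
#' and unit variance by construction. Per group, the per-protein mean z
#' is averaged over pathway members; the group contrast is the mean of
#' the per-protein differences with its 95% t-interval, with pathway
#' member proteins as the unit of replication.
#'
#' @param mat proteins x samples abundance matrix (linear scale; z-scores
#'   are computed on log2 values).
#' @param pathway character vector of member protein ids.
#' @param groups sample -> group labels (2 levels).
#' @param reference reference group (difference = other - reference).
#' @param log_transform standardize log2 abundances (default TRUE).
#' @return object of class `pathway_zscores`: list with `z` (member
#'   z-score matrix), `protein_means` (per protein per group mean z),
#'   `group_means`, `mean_difference`, `conf_int` (95% CI; `NA` with
#'   `singleton = TRUE` for single-protein pathways).
#' @export
pathway_zscores <- function(mat, pathway, groups, reference = NULL,
                            log_transform = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("pathway_zscores() needs 2 groups")
  if (is.null(reference)) reference <- levels(groups)[1L]
  other <- setdiff(levels(groups), reference)
  members <- intersect(pathway, rownames(mat))
  if (!length(members)) stop("pathway has no member in the table")
  x <- mat[members, , drop = FALSE]
  if (log_transform) x <- log2(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  if (any(sdv == 0)) stop("zero-variance protein(s) in pathway: ",
                          paste(members[sdv == 0], collapse = ", "))
  z <- sweep(sweep(x, 1L, mu), 1L, sdv, "/")
  pm <- cbind(ref = rowMeans(z[, groups == reference, drop = FALSE]),
              trt = rowMeans(z[, groups == other, drop = FALSE]))
  diffs <- pm[, "trt"] - pm[, "ref"]
  singleton <- length(members) < 2L
  ci <- if (singleton) {
    c(NA_real_, NA_real_)
  } else if (stats::sd(diffs) == 0) {
    # degenerate interval: all member differences identical
    rep(mean(diffs), 2L)
  } else {
    as.numeric(stats::t.test(diffs)$conf.int)
  }
  structure(list(z = z,
                 protein_means = data.frame(
                   protein_id = members,
                   mean_z_ref = unname(pm[, "ref"]),
                   mean_z_trt = unname(pm[, "trt"]),
                   stringsAsFactors = FALSE),
                 group_means = c(stats::setNames(mean(pm[, "ref"]), reference),
                                 stats::setNames(mean(pm[, "trt"]), other)),
                 mean_difference = mean(diffs),
                 conf_int = ci, singleton = singleton,
                 reference = reference, treatment = other),
            class = "pathway_zscores")
}

#' Read a qPCR Ct table
#'
#' Columns: `animal_id, group, gene, replicate, ct`.
#' @param path CSV path.
#' @return validated data frame of class `qpcr_records`.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$ct <= 0 | df$ct >= 45)) stop("Ct values must lie in (0, 45)")
  class(df) <- c("qpcr_records", "data.frame")
  df
}

#' Relative mtDNA/nDNA copy-number ratio from qPCR Ct values
#'
#' Replicate Ct values are averaged per animal per gene first; the ratio
#' is `2^(mean Ct(nuclear) - mean Ct(mito))` — one Ct cycle difference
#' corresponds to a doubling. Reported relative (no diploidy factor);
#' only between-group contrasts are interpreted.
#'
#' @param records data frame with `animal_id, group, gene, replicate, ct`.
#' @param mito_gene mitochondrial gene (default `"Nd1"`).
#' @param nuclear_gene nuclear reference gene (default `"Lpl"`).
#' @return data frame: animal_id, group, ct_mito, ct_nuclear, ratio.
#' @export
mtdna_ratio <- function(records, mito_gene = "Nd1", nuclear_gene = "Lpl") {
  df <- as.data.frame(records)
  rows <- lapply(split(df, df$animal_id), function(d) {
    for (g in c(mito_gene, nuclear_gene))
      if (!g %in% d$gene)
        stop("animal ", d$animal_id[1L], " is missing gene ", g)
    ctm <- mean(d$ct[d$gene == mito_gene])
    ctn <- mean(d$ct[d$gene == nuclear_gene])
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               ct_mito = ctm, ct_nuclear = ctn,
               ratio = 2^(ctn - ctm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$animal_id), ]
}
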