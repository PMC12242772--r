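#' Filter low-expression features from a merged count table
#'
#' A feature is retained when its group-aggregated CPM reaches
#' `cpmThreshold` in at least `minGroups` groups. Features flagged in
#' `keep` (typically the TERRA regions — the analyte itself) are always
#' retained regardless of expression.
#'
#' @param counts features x samples count matrix (rownames = feature
#'   ids).
#' @param groups character/factor of per-sample group labels (tissue or
#'   cell type), length `ncol(counts)`.
#' @param librarySizes per-sample library sizes for the CPM computation;
#'   defaults to column sums.
#' @param cpmThreshold CPM cutoff, default 1.
#' @param keep logical vector (length `nrow(counts)`) of features to
#'   retain unconditionally, or `NULL`.
#' @param aggregator per-group summary of CPM, `"mean"` (default) or
#'   `"median"`.
#' @param minGroups number of groups that must pass, default 1.
#' @return The filtered count matrix.
#' @export
filterLowExpression <- function(counts, groups,
                                librarySizes = colSums(counts),
                                cpmThreshold = 1, keep = NULL,
                                aggregator = c("mean", "median"),
                                minGroups = 1L) {
    aggregator <- match.arg(aggregator)
    counts <- as.matrix(counts)
    stopifnot(length(groups) == ncol(counts), all(nzchar(as.character(groups))))
    fun <- if (aggregator == "mean") rowMeans else
        function(m) apply(m, 1L, stats::median)
    cpm <- cpmMatrix(counts, pmax(librarySizes, 1))
    groups <- as.character(groups)
    passPerGroup <- vapply(unique(groups), function(g)
        fun(cpm[, groups == g, drop = FALSE]) >= cpmThreshold,
        logical(nrow(counts)))
    pass <- rowSums(as.matrix(passPerGroup)) >= minGroups
    if (!is.null(keep)) pass <- pass | keep
    counts[pass, , drop = FALSE]
}

#' Smooth quantile normalization
#'
#' Normalizes a features x samples expression matrix across sample
#' groups by interpolating, at every rank, between the global quantile
#' reference and the group-specific quantile reference. At rank \eqn{u}:
#' with sorted values \eqn{Q_{u,s}}, overall rank mean \eqn{\bar Q_u},
#' and group rank means \eqn{\bar Q_{g,u}}, the between-group sum of
#' squares \eqn{SSB_u} and total sum of squares \eqn{SST_u} across
#' samples give a raw weight \eqn{1 - SSB_u/SST_u} (set to 1 where
#' \eqn{SST_u = 0}). The weight \eqn{w_u} is the running median of the
#' raw weights over a window of `ceiling(windowFrac * n)` ranks
#' (endpoints copy the nearest computed value), clamped to [0, 1]. The
#' normalized sorted value for a sample in group \eqn{g} is
#' \eqn{w_u \bar Q_u + (1 - w_u)\bar Q_{g,u}}, mapped back to the
#' sample's original feature order; tied input values receive the mean
#' of their tied normalized values.
#'
#' With a single group (or no between-group variation) this reduces
#' exactly to classical quantile normalization. Ranks within each sample
#' are preserved. Normalization operates on the value scale supplied
#' (typically counts); any log transform is left to the caller.
#'
#' @param m features x samples numeric matrix.
#' @param groups per-sample group labels, length `ncol(m)`.
#' @param windowFrac smoothing window as a fraction of the number of
#'   features, default 0.05.
#' @return Matrix of normalized values, same dimensions and dimnames.
#' @export
qsmoothNormalize <- function(m, groups, windowFrac = 0.05) {
    m <- as.matrix(m)
    stopifnot(ncol(m) >= 2L, length(groups) == ncol(m),
              windowFrac > 0, windowFrac <= 1)
    groups <- as.character(groups)
    n <- nrow(m); S <- ncol(m)
    ord <- apply(m, 2L, order)                    # n x S
    Q <- vapply(seq_len(S), function(s) m[ord[, s], s], numeric(n))
    Qbar <- rowMeans(Q)
    glev <- unique(groups)
    Qg <- vapply(glev, function(g)
        rowMeans(Q[, groups == g, drop = FALSE]), numeric(n))  # n x G
    ng <- vapply(glev, function(g) sum(groups == g), numeric(1))
    SSB <- as.numeric((Qg - Qbar)^2 %*% ng)
    SST <- rowSums((Q - Qbar)^2)
    raw <- ifelse(SST == 0, 1, 1 - SSB / SST)
    w <- pmin(1, pmax(0, .runningMedian(raw, ceiling(windowFrac * n))))
    normSorted <- w * Qbar + (1 - w) * Qg[, match(groups, glev), drop = FALSE]
    out <- m
    for (s in seq_len(S)) {
        v <- numeric(n)
        v[ord[, s]] <- normSorted[, s]
        # ties in the input share the mean of their normalized values
        v <- stats::ave(v, m[, s], FUN = mean)
        out[, s] <- v
    }
    out
}
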