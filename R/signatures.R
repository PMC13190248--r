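## Signature exposure refitting (EM for the multinomial mixture with a fixed
## catalogue), catalogue matching by cosine similarity, and probabilistic
## per-mutation attribution.

#' ExposureMatrix: per-sample signature exposure fractions
#'
#' @slot exposures samples x signatures matrix; rows sum to 1.
#' @slot totals per-sample mutation totals used in the fit.
#' @slot loglik per-sample final log-likelihood.
#' @slot converged per-sample convergence flags.
#' @slot nonIdentifiable TRUE when the catalogue contains (numerically)
#'   duplicate columns, making the decomposition non-unique.
#' @export
setClass("ExposureMatrix", representation(
  exposures = "matrix",
  totals = "numeric",
  loglik = "numeric",
  converged = "logical",
  nonIdentifiable = "logical"
))

setValidity("ExposureMatrix", function(object) {
  e <- object@exposures
  if (any(e < -1e-12)) return("exposures must be non-negative")
  if (nrow(e) && any(abs(rowSums(e) - 1) > 1e-9)) {
    return("exposure rows must sum to 1")
  }
  TRUE
})

#' @rdname exposureAccessors
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))
#' ExposureMatrix accessors
#' @param object An \linkS4class{ExposureMatrix}.
#' @return The exposure matrix / totals vector.
#' @name exposureAccessors
#' @export
setMethod("exposures", "ExposureMatrix", function(object) object@exposures)

#' @rdname exposureAccessors
#' @export
setGeneric("exposureTotals", function(object) standardGeneric("exposureTotals"))
#' @rdname exposureAccessors
#' @export
setMethod("exposureTotals", "ExposureMatrix", function(object) object@totals)

setMethod("show", "ExposureMatrix", function(object) {
  cat("ExposureMatrix:", nrow(object@exposures), "samples x",
      ncol(object@exposures), "signatures\n")
  if (object@nonIdentifiable) cat("  WARNING: non-identifiable catalogue\n")
})

## One-sample EM. counts: named vector over the catalogue's channels.
.fit_exposures_one <- function(counts, S, tol = 1e-8, max_iter = 10000L) {
  K <- ncol(S)
  N <- sum(counts)
  e <- rep(1 / K, K)
  nz <- counts > 0
  n_nz <- counts[nz]
  S_nz <- S[nz, , drop = FALSE]
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mix <- as.vector(S_nz %*% e)
    if (any(mix <= 0)) {
      stop("observed channel has zero density under every active signature")
    }
    ll <- sum(n_nz * log(mix))
    # responsibilities: P(signature | channel) weighted by channel counts
    w <- n_nz / mix
    e_new <- e * as.vector(crossprod(S_nz, w)) / N
    e_new <- pmax(e_new, 0)
    e_new <- e_new / sum(e_new)
    if (is.finite(ll_old) && ll < ll_old - 1e-9) {
      stop("EM log-likelihood decreased")   # invariant; should never fire
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      e <- e_new
      converged <- TRUE
      break
    }
    ll_old <- ll
    e <- e_new
  }
  mix <- as.vector(S_nz %*% e)
  list(e = e, loglik = sum(n_nz * log(mix)), converged = converged)
}

#' Fit signature exposures by maximum likelihood
#'
#' Refits the exposure weights of a fixed signature catalogue to observed
#' channel counts under the multinomial mixture model, by EM to convergence
#' (tolerance 1e-8 on the log-likelihood, iteration cap 10,000). Equivalent in
#' the large-count limit to non-negative least squares on frequencies.
#'
#' @param counts Named count vector over the catalogue's channel set, or a
#'   samples x channels matrix with rownames as sample ids.
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @return An \linkS4class{ExposureMatrix}.
#' @export
fitExposures <- function(counts, catalog) {
  S <- signatureProfiles(catalog)
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list("sample1", names(counts)))
  }
  if (ncol(counts) != nrow(S)) {
    stop("channel-set mismatch: counts have ", ncol(counts),
         " channels, catalogue has ", nrow(S))
  }
  if (!is.null(colnames(counts)) && !identical(colnames(counts), rownames(S))) {
    if (!all(colnames(counts) %in% rownames(S))) {
      stop("channel-set mismatch: count channel names not in catalogue")
    }
    counts <- counts[, rownames(S), drop = FALSE]
  }
  # duplicate (or numerically identical) columns make weights non-unique
  cos_pair <- crossprod(S) / outer(sqrt(colSums(S^2)), sqrt(colSums(S^2)))
  diag(cos_pair) <- 0
  non_ident <- any(cos_pair > 1 - 1e-12)
  if (non_ident) {
    warning("catalogue contains identical signature columns; ",
            "exposures are non-identifiable")
  }
  n <- nrow(counts)
  E <- matrix(0, n, ncol(S), dimnames = list(rownames(counts), colnames(S)))
  ll <- numeric(n); conv <- logical(n); tot <- numeric(n)
  for (i in seq_len(n)) {
    ci <- counts[i, ]
    if (sum(ci) <= 0) stop("all-zero channel counts for sample ", rownames(counts)[i])
    fit <- .fit_exposures_one(ci, S)
    E[i, ] <- fit$e
    ll[i] <- fit$loglik
    conv[i] <- fit$converged
    tot[i] <- sum(ci)
  }
  new("ExposureMatrix", exposures = E, totals = tot, loglik = ll,
      converged = conv, nonIdentifiable = non_ident)
}

#' Fit exposures with group-level catalogue restriction
#'
#' Maximum-likelihood refitting of a large fixed catalogue against individual
#' samples leaks exposure mass onto absent signatures when per-sample counts
#' are small. This two-stage fit first pools counts within each group (for
#' example a tissue), fits the pooled profile, keeps only signatures whose
#' pooled exposure exceeds \code{min_exposure}, and then refits each sample of
#' the group against the restricted catalogue. Dropped signatures report
#' exposure zero.
#'
#' @param counts samples x channels count matrix (rownames = sample ids).
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param groups Grouping vector along the rows (default: one group).
#' @param min_exposure Pooled-exposure threshold for keeping a signature
#'   (default 0.01).
#' @param prune_threshold,prune_alpha After the per-sample fit, signatures
#'   with exposure below \code{prune_threshold} whose removal is not rejected
#'   by a chi-squared(1) likelihood-ratio test at \code{prune_alpha} are
#'   dropped (smallest first) and the sample refitted; this removes the
#'   positive floor that boundary-constrained fits put on absent signatures.
#'   Set \code{prune_threshold = 0} to disable.
#' @return An \linkS4class{ExposureMatrix} over the full signature set.
#' @export
fitExposuresRestricted <- function(counts, catalog, groups = NULL,
                                   min_exposure = 0.01,
                                   prune_threshold = 0.02,
                                   prune_alpha = 0.05) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list("sample1", names(counts)))
  }
  if (is.null(groups)) groups <- rep("all", nrow(counts))
  S <- signatureProfiles(catalog)
  E <- matrix(0, nrow(counts), ncol(S),
              dimnames = list(rownames(counts), colnames(S)))
  ll <- numeric(nrow(counts)); conv <- logical(nrow(counts))
  tot <- rowSums(counts)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    pooled <- colSums(counts[rows, , drop = FALSE])
    pooled_fit <- fitExposures(matrix(pooled, nrow = 1,
                                      dimnames = list("pooled", names(pooled))),
                               catalog)
    active <- colnames(S)[exposures(pooled_fit)[1, ] > min_exposure]
    if (length(active) < 1) active <- colnames(S)
    sub_cat <- SignatureCatalog(S[, active, drop = FALSE],
                                channelSet = channelSet(catalog))
    fit <- fitExposures(counts[rows, , drop = FALSE], sub_cat)
    E[rows, active] <- exposures(fit)
    ll[rows] <- fit@loglik
    conv[rows] <- fit@converged
    if (prune_threshold > 0) {
      crit <- stats::qchisq(1 - prune_alpha, 1)
      for (r in rows) {
        act_r <- active
        e_r <- E[r, act_r]
        ll_r <- ll[r]
        repeat {
          if (length(act_r) <= 1) break
          small <- act_r[e_r[act_r] < prune_threshold]
          if (!length(small)) break
          k <- small[which.min(e_r[small])]
          cand <- setdiff(act_r, k)
          f2 <- tryCatch(fitExposures(
            counts[r, , drop = FALSE],
            SignatureCatalog(S[, cand, drop = FALSE],
                             channelSet = channelSet(catalog))),
            error = function(e) NULL)
          if (is.null(f2) || 2 * (ll_r - f2@loglik) > crit) break
          act_r <- cand
          e_r <- stats::setNames(numeric(ncol(S)), colnames(S))
          e_r[cand] <- exposures(f2)[1, ]
          ll_r <- f2@loglik
        }
        E[r, ] <- 0
        E[r, act_r] <- e_r[act_r]
        ll[r] <- ll_r
      }
    }
  }
  new("ExposureMatrix", exposures = E, totals = tot, loglik = ll,
      converged = conv, nonIdentifiable = FALSE)
}

#' Cosine similarity between two non-negative profiles
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in [0, 1] for non-negative inputs.
#' @export
cosineSimilarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match a profile to a reference catalogue
#'
#' Reports the best cosine match; matches at or above the threshold take the
#' reference label, otherwise the next free alphabetical label for the channel
#' set (SBS-A, SBS-B, ...) is assigned.
#'
#' @param profile Normalised channel profile (named or catalogue order).
#' @param catalog Reference \linkS4class{SignatureCatalog}.
#' @param threshold Cosine similarity threshold (default 0.9); a match
#'   requires similarity strictly higher than the threshold.
#' @param taken Character vector of already-assigned novel labels.
#' @return list(matched, label, best_match, cosine).
#' @export
matchToCatalog <- function(profile, catalog, threshold = 0.9,
                           taken = character(0)) {
  S <- signatureProfiles(catalog)
  if (!ncol(S)) stop("empty catalogue")
  if (!is.null(names(profile))) profile <- profile[rownames(S)]
  sims <- apply(S, 2, cosineSimilarity, b = profile)
  best <- which.max(sims)
  if (sims[best] > threshold) {
    return(list(matched = TRUE, label = colnames(S)[best],
                best_match = colnames(S)[best], cosine = unname(sims[best])))
  }
  prefix <- switch(channelSet(catalog), SBS96 = "SBS-", SBS192 = "SBS-",
                   DBS78 = "DBS-", ID83 = "ID-")
  candidates <- paste0(prefix, LETTERS)
  free <- setdiff(candidates, c(colnames(S), taken))
  list(matched = FALSE, label = free[1], best_match = colnames(S)[best],
       cosine = unname(sims[best]))
}

#' Attribute individual mutations to signatures
#'
#' For a mutation in channel c of sample s, the posterior probability of
#' signature k is e_sk * S_kc / sum_j e_sj * S_jc.
#'
#' @param variants Channelized variant table (see \link{channelizeVariants})
#'   restricted to the catalogue's channel set.
#' @param exposureMatrix An \linkS4class{ExposureMatrix} with one row per
#'   sample present in \code{variants}.
#' @param catalog The \linkS4class{SignatureCatalog} used for the fit.
#' @return list with \code{probabilities} (mutations x signatures matrix,
#'   rows sum to 1) and \code{argmax} (most likely signature per mutation).
#' @export
attributeMutations <- function(variants, exposureMatrix, catalog) {
  v <- asVariantTable(variants)
  S <- signatureProfiles(catalog)
  E <- exposures(exposureMatrix)
  keep <- !is.na(v$channel_set) & v$channel_set == channelSet(catalog)
  v <- v[keep, , drop = FALSE]
  P <- matrix(NA_real_, nrow(v), ncol(S),
              dimnames = list(NULL, colnames(S)))
  if (any(!v$sample_id %in% rownames(E))) {
    stop("no exposures fitted for sample ",
         setdiff(v$sample_id, rownames(E))[1])
  }
  # the posterior depends only on (sample, channel): compute per group
  grp <- paste(v$sample_id, v$channel)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    s <- v$sample_id[rows[1]]
    dens <- E[s, ] * S[v$channel[rows[1]], ]
    tot <- sum(dens)
    if (tot <= 0) {
      stop("channel ", v$channel[rows[1]],
           " has zero total density in sample ", s)
    }
    P[rows, ] <- matrix(dens / tot, length(rows), ncol(S), byrow = TRUE)
  }
  list(variants = v, probabilities = P,
       argmax = colnames(S)[max.col(P, ties.method = "first")])
}

#' Fraction of driver mutations attributable to a signature
#'
#' Sums per-driver-mutation posterior probabilities for the target signature.
#' The attributed count is reported both unrounded and rounded half-up (the
#' convention used when printing integer numerators).
#'
#' @param attribution Result of \link{attributeMutations} run on the driver
#'   mutation set.
#' @param targetSignature Signature name.
#' @return list(attributed, attributed_rounded, total, fraction); when the
#'   driver set is empty, fraction is NA ("not applicable").
#' @export
attributeDriverFractions <- function(attribution, targetSignature) {
  P <- attribution$probabilities
  total <- nrow(P)
  if (!total) {
    return(list(attributed = NA_real_, attributed_rounded = NA_integer_,
                total = 0L, fraction = NA_real_))
  }
  att <- sum(P[, targetSignature])
  list(attributed = att,
       attributed_rounded = as.integer(floor(att + 0.5)),
       total = total,
       fraction = att / total)
}
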