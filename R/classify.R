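#' Construct a haplotype record from motif strings
#'
#' Convenience constructor used in examples, tests and the simulator: a
#' haplotype is its parsed HVS-I calls, optionally parsed HVS-II calls and
#' coding-region calls. \code{NULL} marks a segment as not typed, which is
#' different from typed-with-no-variants (an empty string).
#'
#' @param hvs1 HVS-I motif (minus 16000), possibly empty.
#' @param hvs2 HVS-II motif or NULL (untyped).
#' @param coding coding-region motif or NULL (untyped).
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return list with elements hvs1, hvs2, coding (call data.frames or NULL).
#' @export
haplotypeFromMotifs <- function(hvs1 = "", hvs2 = NULL, coding = NULL,
                                ref = rCRSAnnotation()) {
    list(hvs1 = parseMotif(hvs1, "HVS1", ref),
         hvs2 = if (is.null(hvs2)) NULL else {
             calls <- parseMotif(hvs2, "HVS2", ref)
             for (p in c(73L, 263L))
                 if (!p %in% calls$position)
                     calls <- rbind(calls, data.frame(
                         position = p, ref = refBase(ref, p),
                         event = "transition",
                         derived = transitionPartner(refBase(ref, p)),
                         back = FALSE, stringsAsFactors = FALSE))
             calls[order(calls$position), , drop = FALSE]
         },
         coding = if (is.null(coding)) NULL
                  else parseMotif(coding, "coding", ref))
}

# Score one haplotype against one clade profile.
# Scoring: a visible expected diagnostic matched in state contributes +w,
# observed at the position with a different derived state +w/2, absent or
# explicitly reverted ("@") -min(w, 1). A satisfied back-mutation
# diagnostic contributes +w (its absence is evidence), a violated one
# -min(w, 1); a violated anti-diagnostic -min(w, 1) (its absence is
# neutral). The penalty cap makes high-weight diagnostics strong evidence
# when observed without making their absence worse than any other single
# missing mutation. Diagnostics in untyped segments are skipped entirely.
#' @keywords internal
scoreProfile <- function(calls, typed, prof) {
    lookup <- function(pos) {
        hit <- calls[calls$position == pos & calls$event != "insertion", ,
                     drop = FALSE]
        if (nrow(hit)) hit[1, ] else NULL
    }
    score <- 0; matchedW <- 0
    matched <- 0L; missing <- 0L; halves <- 0L; violations <- 0L
    levelMiss <- list()
    bump <- function(lv) {
        levelMiss[[lv]] <<- (if (is.null(levelMiss[[lv]])) 0L
                             else levelMiss[[lv]]) + 1L
    }
    ex <- prof$expect
    for (i in seq_len(nrow(ex))) {
        if (!typed[[ex$segment[i]]]) next
        w <- ex$weight[i]
        call <- lookup(ex$position[i])
        if (is.null(call) || call$back) {
            score <- score - min(w, 1); missing <- missing + 1L
            bump(ex$level[i])
        } else if (call$derived == ex$derived[i] &&
                   call$event == ex$event[i]) {
            score <- score + w; matchedW <- matchedW + w
            matched <- matched + 1L
        } else {
            score <- score + w / 2; matchedW <- matchedW + w / 2
            halves <- halves + 1L
        }
    }
    bk <- prof$backs
    for (i in seq_len(nrow(bk))) {
        if (!typed[[bk$segment[i]]]) next
        w <- bk$weight[i]
        call <- lookup(bk$position[i])
        if (is.null(call) || call$back) {
            score <- score + w; matchedW <- matchedW + w
            matched <- matched + 1L
        } else {
            # violations penalise the score but do not make the clade
            # inadmissible: a retained ancestral state under a soft back
            # diagnostic is weaker evidence than a missing diagnostic
            score <- score - min(w, 1); violations <- violations + 1L
        }
    }
    an <- prof$antis
    for (i in seq_len(nrow(an))) {
        if (!typed[[an$segment[i]]]) next
        call <- lookup(an$position[i])
        if (!is.null(call) && !call$back) {
            score <- score - min(an$weight[i], 1)
            violations <- violations + 1L
        }
    }
    explained <- unique(c(ex$position, bk$position, an$position))
    extra <- sum(!calls$position %in% explained)
    list(score = score, matchedW = matchedW, matched = matched,
         missing = missing, halves = halves, violations = violations,
         extra = extra,
         maxLevelMiss = if (length(levelMiss))
             max(unlist(levelMiss)) else 0L)
}

#' Assign a haplotype to its finest subclade
#'
#' Implements the motif matching and near-matching strategy: every clade's
#' accumulated root-to-clade expectation (restricted to the segments the
#' record was typed for) is scored against the haplotype, and the
#' best-scoring admissible clade wins. In \code{near} mode a clade remains
#' admissible while no single clade level has more than
#' \code{nearTolerance} missing/violated diagnostics; private mutations are
#' not penalised. In \code{strict} mode only clades whose visible profile
#' is matched perfectly are admissible. Ties between a clade and its
#' ancestor resolve to the deeper clade (an HVS-only record cannot display
#' purely coding diagnostics, and is assigned to the finest compatible
#' subclade, which is how published motif tables are labelled); ties
#' between unrelated clades resolve to their most recent common ancestor
#' with status \code{ambiguous}.
#'
#' @param h a haplotype as returned by \code{\link{haplotypeFromMotifs}}
#'   (elements hvs1, hvs2, coding; NULL = untyped).
#' @param tree a \linkS4class{HaplogroupTree}.
#' @param mode \code{"near"} (default) or \code{"strict"}.
#' @param nearTolerance per-level missing tolerance; default from the tree
#'   config.
#' @return one-row data.frame: clade, status (exact/near/ambiguous/
#'   unassigned), score, matched, missing, extraPrivate.
#' @export
assignClade <- function(h, tree, mode = c("near", "strict"),
                        nearTolerance = tree@nearTolerance) {
    mode <- match.arg(mode)
    typed <- list(HVS1 = !is.null(h$hvs1), HVS2 = !is.null(h$hvs2),
                  coding = !is.null(h$coding))
    calls <- do.call(rbind, Filter(Negate(is.null),
                                   list(h$hvs1, h$hvs2, h$coding)))
    if (is.null(calls)) calls <- emptyCalls()
    cl <- tree@clades
    sc <- lapply(cl$name, function(nm)
        scoreProfile(calls, typed, tree@profiles[[nm]]))
    names(sc) <- cl$name
    admissible <- vapply(cl$name, function(nm) {
        s <- sc[[nm]]
        if (mode == "strict")
            s$missing == 0L && s$halves == 0L && s$violations == 0L
        else s$maxLevelMiss <= nearTolerance
    }, logical(1))
    admissible[cl$depth == 0L] <- TRUE
    cand <- cl$name[admissible]
    score <- vapply(cand, function(nm) sc[[nm]]$score, numeric(1))
    matchedW <- vapply(cand, function(nm) sc[[nm]]$matchedW, numeric(1))
    depth <- cl$depth[match(cand, cl$name)]
    best <- cand[score == max(score)]
    if (length(best) > 1L) {
        mw <- matchedW[match(best, cand)]
        best <- best[mw == max(mw)]
    }
    if (length(best) > 1L) {
        dp <- depth[match(best, cand)]
        best <- best[dp == max(dp)]
    }
    status <- NA_character_
    if (length(best) > 1L) {
        # unrelated clades tied: do not descend past their common ancestor
        paths <- lapply(best, ancestorClades, tree = tree)
        common <- Reduce(intersect, paths)
        best <- common[length(common)]
        status <- "ambiguous"
    }
    s <- sc[[best]]
    if (best == rootClade(tree) || s$score <= 0) {
        best <- rootClade(tree); status <- "unassigned"; s <- sc[[best]]
    } else if (is.na(status)) {
        status <- if (s$missing == 0L && s$halves == 0L &&
                      s$violations == 0L) "exact" else "near"
    }
    data.frame(clade = best, status = status, score = s$score,
               matched = s$matched, missing = s$missing,
               extraPrivate = s$extra, stringsAsFactors = FALSE)
}

#' Classify every record of a haplotype table
#'
#' Assigns each record of a \linkS4class{HaplotypeSet} and reports
#' concordance with the recorded haplogroup labels. Records whose
#' assignment disagrees with their recorded label are flagged (message),
#' never dropped.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param tree a \linkS4class{HaplogroupTree}.
#' @param mode passed to \code{\link{assignClade}}.
#' @param quiet suppress per-record discordance messages.
#' @return data.frame with one row per record (id, recorded, assigned,
#'   status, score, matched, missing, extraPrivate, n, population, region,
#'   source) and attributes \code{concordance} (fraction of rows whose
#'   assignment equals the recorded label) and \code{cladeCounts} (named,
#'   weighted by n).
#' @export
classifyTable <- function(haps, tree, mode = c("near", "strict"),
                          quiet = FALSE) {
    mode <- match.arg(mode)
    d <- haplotypes(haps)
    if (!nrow(d)) stop("empty haplotype set")
    res <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
        assignClade(list(hvs1 = d$hvs1[[i]], hvs2 = d$hvs2[[i]],
                         coding = NULL), tree, mode)))
    out <- data.frame(id = d$id, recorded = d$recorded,
                      assigned = res$clade, status = res$status,
                      score = res$score, matched = res$matched,
                      missing = res$missing,
                      extraPrivate = res$extraPrivate,
                      n = d$n, population = d$population,
                      region = d$region, source = d$source,
                      stringsAsFactors = FALSE)
    disc <- which(out$recorded != out$assigned & nzchar(out$recorded))
    if (length(disc) && !quiet)
        for (i in disc)
            message("discordant assignment: record ", out$id[i],
                    " recorded ", out$recorded[i], " assigned ",
                    out$assigned[i])
    attr(out, "concordance") <-
        mean(out$assigned[nzchar(out$recorded)] ==
             out$recorded[nzchar(out$recorded)])
    attr(out, "cladeCounts") <- tapply(out$n, out$assigned, sum)
    out
}

#' Concordance of a classification with the recorded labels
#' @param assignments result of \code{\link{classifyTable}}.
#' @export
concordance <- function(assignments) attr(assignments, "concordance")

#' Weighted count of records assigned to a clade
#'
#' Sums the table's N column over records assigned to \code{clade},
#' optionally including its descendant subclades.
#'
#' @param assignments result of \code{\link{classifyTable}}.
#' @param tree the \linkS4class{HaplogroupTree} used.
#' @param clade clade name.
#' @param includeDescendants include descendant subclades (default TRUE).
#' @return integer count of individuals.
#' @export
cladeCount <- function(assignments, tree, clade, includeDescendants = TRUE) {
    clades <- if (includeDescendants) descendantClades(tree, clade)
              else clade
    sum(assignments$n[assignments$assigned %in% clades])
}
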