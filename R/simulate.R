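#' Simulation configuration
#'
#' Validated configuration for the ground-truth generator. Defaults mirror
#' the study conditions of the shipped analyses: 19 sampled mtDNAs, a
#' root age of 23,541 years (the whole-clade coding-clock age), and
#' class-specific mutation rates expressed as years per mutation. The
#' three mutation classes are disjoint by construction:
#' \code{synonymous_transition} mutations are placed on the exactly
#' enumerated synonymous-transition site set,
#' \code{coding_substitution} mutations on the remaining coding-window
#' sites (so the "all coding substitutions" clock counts both classes, at
#' an implied rate given by \code{\link{impliedYearsPerMutation}}), and
#' \code{control} mutations on the control-region windows minus the
#' excluded sites and poly(C) tracts.
#'
#' @param seed integer RNG seed.
#' @param topology \code{"star"}, \code{"yule"} or \code{"newick"}.
#' @param newick Newick string (with branch lengths) for
#'   \code{topology = "newick"}; depths are rescaled to \code{tmrcaYears}.
#' @param nTips number of sampled mtDNAs (>= 2).
#' @param tmrcaYears true root age in years.
#' @param rates named positive numeric: years per mutation for
#'   coding_substitution, synonymous_transition, control.
#' @param regionalSampling named probabilities (summing to 1) for sampling
#'   origins in motif-table emission.
#' @param cladePlan named integer vector (clade -> record count) for
#'   motif-table emission.
#' @param privateRate Poisson mean of private control-region mutations per
#'   emitted motif record.
#' @param maxPrivate cap on private mutations per record.
#' @param backMutations plant occasional reversions of ancestral mutations
#'   (the classifier's and network's hard case); off by default.
#' @return list of class \code{mtn1aSimConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             topology = c("star", "yule", "newick"),
                             newick = NULL, nTips = 19L,
                             tmrcaYears = 23541,
                             rates = c(coding_substitution = 21408,
                                       synonymous_transition = 6764,
                                       control = 20180),
                             regionalSampling = c(`Eastern Europe` = 0.3,
                                                  `Central Europe` = 0.2,
                                                  `Central Asia` = 0.3,
                                                  `Near East` = 0.2),
                             cladePlan = NULL, privateRate = 0.5,
                             maxPrivate = 2L, backMutations = FALSE) {
    topology <- match.arg(topology)
    stopifnot(nTips >= 2L, tmrcaYears >= 0, all(rates > 0))
    need <- c("coding_substitution", "synonymous_transition", "control")
    if (!all(need %in% names(rates)))
        stop("rates must name ", paste(need, collapse = ", "))
    if (abs(sum(regionalSampling) - 1) > 1e-9)
        stop("regional sampling probabilities must sum to 1")
    if (topology == "newick" && is.null(newick))
        stop("topology 'newick' needs a newick string")
    structure(list(seed = as.integer(seed), topology = topology,
                   newick = newick, nTips = as.integer(nTips),
                   tmrcaYears = tmrcaYears, rates = rates,
                   regionalSampling = regionalSampling,
                   cladePlan = cladePlan, privateRate = privateRate,
                   maxPrivate = as.integer(maxPrivate),
                   backMutations = isTRUE(backMutations)),
              class = "mtn1aSimConfig")
}

#' Implied clock rate of a simulation configuration
#'
#' Years per counted mutation for a given clock under the configured
#' class rates: the synonymous clock sees only the synonymous_transition
#' class; the all-coding clock sees both coding classes, so its implied
#' rate is the harmonic combination of the two.
#' @param cfg a \code{\link{simulationConfig}}.
#' @param clock \code{"all_coding"} or \code{"synonymous_transition"}.
#' @export
impliedYearsPerMutation <- function(cfg,
                                    clock = c("all_coding",
                                              "synonymous_transition")) {
    clock <- match.arg(clock)
    r <- cfg$rates
    if (clock == "synonymous_transition")
        unname(r["synonymous_transition"])
    else unname(1 / (1 / r["coding_substitution"] +
                     1 / r["synonymous_transition"]))
}

#' @keywords internal
legalSiteSets <- function(ref) {
    if (!is.null(ref@cache$legalSets)) return(ref@cache$legalSets)
    ctrl <- c(seq(ref@hvs1Window[1], ref@hvs1Window[2]),
              seq(ref@hvs2Window[1], ref@hvs2Window[2]))
    ctrl <- setdiff(ctrl, ref@excludedSites)
    ctrl <- ctrl[!inPolyCTract(ref, ctrl)]
    syn <- synonymousTransitionSites(ref)
    coding <- seq(ref@codingWindow[1], ref@codingWindow[2])
    coding <- setdiff(setdiff(coding, syn), ref@excludedSites)
    ref@cache$legalSets <- list(control = ctrl,
                                synonymous_transition = syn,
                                coding_substitution = coding)
    ref@cache$legalSets
}

#' Simulate a genealogy with planted mutations
#'
#' Draws a genealogy of the configured topology with branch lengths in
#' years, then plants Poisson(length/rate) mutations per class on every
#' edge, with positions drawn uniformly (without replacement across the
#' whole genealogy, so the data are homoplasy-free unless
#' \code{backMutations} is requested) from the class's legal site set.
#' All planted mutations are transitions; each carries its realised
#' functional class.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return a \linkS4class{GroundTruth}.
#' @export
simulateGenealogy <- function(cfg, ref = rCRSAnnotation()) {
    set.seed(cfg$seed)
    sets <- legalSiteSets(ref)
    for (k in names(sets))
        if (!length(sets[[k]]))
            stop("empty legal site set for class ", k)
    # topology as (nodeId, parent, lengthYears) in preorder
    if (cfg$topology == "star") {
        nodeId <- c("root", paste0("t", seq_len(cfg$nTips)))
        parent <- c(0L, rep(1L, cfg$nTips))
        len <- c(0, rep(cfg$tmrcaYears, cfg$nTips))
    } else {
        phy <- if (cfg$topology == "yule")
            ape::rphylo(cfg$nTips, birth = 1, death = 0)
        else ape::read.tree(text = cfg$newick)
        if (is.null(phy$edge.length))
            stop("newick topology needs branch lengths")
        depth <- max(ape::node.depth.edgelength(phy))
        if (depth > 0)
            phy$edge.length <- phy$edge.length * cfg$tmrcaYears / depth
        ntip <- length(phy$tip.label)
        rootN <- ntip + 1L
        ord <- rootN
        queue <- rootN
        par <- stats::setNames(rep(NA_integer_, ntip + phy$Nnode),
                               seq_len(ntip + phy$Nnode))
        elen <- stats::setNames(rep(0, ntip + phy$Nnode),
                                seq_len(ntip + phy$Nnode))
        while (length(queue)) {
            cur <- queue[1]; queue <- queue[-1]
            kids <- phy$edge[phy$edge[, 1] == cur, 2]
            for (ki in seq_along(kids)) {
                k2 <- kids[ki]
                par[as.character(k2)] <- cur
                elen[as.character(k2)] <-
                    phy$edge.length[phy$edge[, 1] == cur][ki]
                ord <- c(ord, k2)
                queue <- c(queue, k2)
            }
        }
        lab <- ifelse(ord <= ntip, phy$tip.label[pmin(ord, ntip)],
                      ifelse(ord == rootN, "root", paste0("n", ord)))
        nodeId <- lab
        parent <- match(par[as.character(ord)], ord)
        parent[1] <- 0L
        len <- unname(elen[as.character(ord)])
    }
    isTip <- !seq_along(nodeId) %in% parent
    used <- integer(0)
    calls <- vector("list", length(nodeId))
    calls[[1]] <- simCallRow()[0, ]
    for (i in seq_along(nodeId)[-1]) {
        rows <- list()
        for (k in c("control", "synonymous_transition",
                    "coding_substitution")) {
            lam <- len[i] / cfg$rates[[k]]
            nk <- stats::rpois(1L, lam)
            if (!nk) next
            avail <- setdiff(sets[[k]], used)
            if (nk > length(avail))
                stop("legal site set for ", k, " exhausted")
            pos <- sort(sample(avail, nk))
            used <- c(used, pos)
            rb <- refBase(ref, pos)
            cc <- data.frame(position = pos, ref = rb,
                             event = "transition",
                             derived = transitionPartner(rb),
                             back = FALSE, stringsAsFactors = FALSE)
            cc$site <- siteLabel(cc)
            cc$class <- classifyMutation(cc, ref)
            rows[[length(rows) + 1L]] <- cc
        }
        cc <- if (length(rows)) do.call(rbind, rows) else simCallRow()[0, ]
        if (cfg$backMutations && stats::runif(1) < 0.1) {
            anc <- ancestralCallsAt(calls, parent, i)
            if (base::nrow(anc)) {
                rev1 <- anc[sample(base::nrow(anc), 1L), , drop = FALSE]
                rev1$back <- TRUE
                cc <- rbind(cc, rev1)
            }
        }
        calls[[i]] <- cc[order(cc$position), , drop = FALSE]
    }
    tree <- mutationTree(nodeId = nodeId, parent = parent,
                         edgeCalls = calls, sampled = isTip,
                         multiplicity = as.numeric(isTip))
    new("GroundTruth", tree = tree, tmrcaYears = cfg$tmrcaYears,
        config = unclass(cfg))
}

#' @keywords internal
simCallRow <- function() {
    data.frame(position = integer(0), ref = character(0),
               event = character(0), derived = character(0),
               back = logical(0), site = character(0),
               class = character(0), stringsAsFactors = FALSE)
}

#' @keywords internal
ancestralCallsAt <- function(calls, parent, i) {
    anc <- simCallRow()[0, ]
    j <- parent[i]
    while (j > 0L) {
        anc <- rbind(anc, calls[[j]][!calls[[j]]$back, , drop = FALSE])
        j <- parent[j]
    }
    anc
}

#' Root-to-tip call sets of a mutation tree
#'
#' Accumulates each sampled node's mutations along its root-to-node path;
#' a back-mutation call cancels the corresponding ancestral call.
#' @param tree a \linkS4class{MutationTree}.
#' @return named list of mutation-call data.frames.
#' @export
tipCallSets <- function(tree) {
    n <- length(tree@nodeId)
    acc <- vector("list", n)
    acc[[1]] <- tree@edgeCalls[[1]][0, , drop = FALSE]
    for (i in seq_len(n)[-1]) {
        cc <- rbind(acc[[tree@parent[i]]], tree@edgeCalls[[i]])
        if (any(cc$back)) {
            rm <- cc$position[cc$back]
            cc <- cc[!cc$position %in% rm, , drop = FALSE]
        }
        acc[[i]] <- cc[order(cc$position), , drop = FALSE]
    }
    out <- acc[tree@sampled]
    names(out) <- tree@nodeId[tree@sampled]
    out
}

#' Emit simulated mitogenome sequences
#'
#' Applies each sampled haplotype's root-to-tip mutations to the reference
#' and optionally writes a FASTA plus a truth table listing every planted
#' call.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param fastaPath,truthPath optional output files.
#' @return (invisibly) list with \code{sequences} (named character) and
#'   \code{truth} (data.frame).
#' @export
emitSequences <- function(gt, ref = rCRSAnnotation(), fastaPath = NULL,
                          truthPath = NULL) {
    tips <- tipCallSets(gt@tree)
    seqs <- vapply(tips, function(cc) applyMutations(ref, cc),
                   character(1))
    truth <- do.call(rbind, lapply(names(tips), function(id) {
        cc <- tips[[id]]
        if (!base::nrow(cc)) return(NULL)
        data.frame(tip = id, position = cc$position, ref = cc$ref,
                   event = cc$event, derived = cc$derived,
                   class = if ("class" %in% names(cc)) cc$class else NA,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(truth))
        truth <- data.frame(tip = character(0), position = integer(0),
                            ref = character(0), event = character(0),
                            derived = character(0), class = character(0))
    if (!is.null(fastaPath)) {
        ss <- Biostrings::DNAStringSet(seqs)
        Biostrings::writeXStringSet(ss, fastaPath)
    }
    if (!is.null(truthPath))
        utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(list(sequences = seqs, truth = truth))
}

#' Emit a Table-1-style motif table with known clade labels
#'
#' For every (clade, count) entry of the configuration's clade plan,
#' emits records carrying the clade's full control-region diagnostic
#' profile plus Poisson private control mutations (drawn away from every
#' diagnostic position in the tree, so planted labels remain
#' recoverable), with sampling origins drawn from the configured regional
#' probabilities. The haplogroup column carries the true label.
#'
#' @param cfg a \code{\link{simulationConfig}} with a \code{cladePlan}.
#' @param tree a \linkS4class{HaplogroupTree}.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param path optional output TSV.
#' @return (invisibly) the emitted data.frame.
#' @export
emitMotifTable <- function(cfg, tree = loadCladeTree(ref = ref),
                           ref = rCRSAnnotation(), path = NULL) {
    set.seed(cfg$seed)
    plan <- cfg$cladePlan
    if (is.null(plan)) plan <- integer(0)
    unknown <- setdiff(names(plan), cladeNames(tree))
    if (length(unknown))
        stop("clade plan references unknown clade(s): ",
             paste(unknown, collapse = ", "))
    diagPos <- unique(unlist(lapply(tree@profiles, function(p)
        c(p$expect$position, p$backs$position, p$antis$position))))
    ctrl <- legalSiteSets(ref)$control
    privatePool <- setdiff(ctrl[ctrl >= ref@hvs1Window[1]], diagPos)
    rows <- list()
    for (clade in names(plan)) {
        prof <- tree@profiles[[clade]]
        ex1 <- prof$expect[prof$expect$segment == "HVS1", , drop = FALSE]
        ex2 <- prof$expect[prof$expect$segment == "HVS2" &
                           prof$expect$weight > 0, , drop = FALSE]
        baseCalls <- data.frame(position = ex1$position,
                                ref = refBase(ref, ex1$position),
                                event = ex1$event, derived = ex1$derived,
                                back = FALSE, stringsAsFactors = FALSE)
        hvs2Motif <- if (base::nrow(ex2))
            formatMotif(data.frame(position = ex2$position,
                                   ref = refBase(ref, ex2$position),
                                   event = ex2$event,
                                   derived = ex2$derived, back = FALSE,
                                   stringsAsFactors = FALSE),
                        "HVS2", ref)
        else ""
        for (r in seq_len(plan[[clade]])) {
            k <- min(stats::rpois(1L, cfg$privateRate), cfg$maxPrivate)
            cc <- baseCalls
            if (k > 0L) {
                pos <- sample(setdiff(privatePool, cc$position), k)
                rb <- refBase(ref, pos)
                cc <- rbind(cc, data.frame(
                    position = pos, ref = rb, event = "transition",
                    derived = transitionPartner(rb), back = FALSE,
                    stringsAsFactors = FALSE))
            }
            rows[[length(rows) + 1L]] <- data.frame(
                haplogroup = clade,
                hvs1_motif = formatMotif(cc, "HVS1", ref),
                hvs2_motif = hvs2Motif, n = 1L,
                population = sample(names(cfg$regionalSampling), 1L,
                                    prob = cfg$regionalSampling),
                region = NA_character_, source = "simulated",
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(haplogroup = character(0),
                           hvs1_motif = character(0),
                           hvs2_motif = character(0), n = integer(0),
                           population = character(0),
                           region = character(0), source = character(0),
                           stringsAsFactors = FALSE)
    out$region <- out$population
    if (!is.null(path))
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(out)
}

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nSampled(object@tree), "tips, TMRCA",
        object@tmrcaYears, "years,", parsimonyScore(object@tree),
        "planted mutations\n")
})
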