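#' Load a haplogroup definition tree
#'
#' Reads a clade-definition config (YAML) into a validated
#' \linkS4class{HaplogroupTree}. Each clade names its parent and the
#' diagnostic mutations it introduces, written in motif nomenclature under
#' the keys \code{hvs1}, \code{hvs2} and \code{coding} (HVS-I tokens minus
#' 16000). A token with an \code{@} prefix declares a back-mutation
#' diagnostic: the ancestral diagnostic at that position is expected to
#' have reverted. \code{anti_hvs1}/\code{anti_hvs2}/\code{anti_coding}
#' list mutations whose presence argues against the clade. A per-clade
#' \code{weights} map (keyed by the literal token) downweights
#' hypervariable or upweights highly specific diagnostics; the default
#' weight is 1.
#'
#' The shipped default encodes the N1a subclade phylogeny: the basal N1a
#' control motif 16147G-16172-16223-16248-16355; N1a1 replacing 16147G by
#' 16147A and adding coding 3336; N1a1a adding 16320; N1a1a1 adding the
#' purely coding diagnostics 8164, 9300 and the back mutation at 2702;
#' N1a1a1a adding 16189 (hypervariable, downweighted) and coding 6641;
#' N1a1a2 adding 16086 with a reverted 16172 and the HVS-II motif
#' 152-199-204-207 (207 is the specific marker); N1a1a3 adding 16154; and
#' N1a1b as the N1a1 branch lacking 16320.
#'
#' @param config path to a YAML clade config; default the packaged N1a
#'   tree.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return a \linkS4class{HaplogroupTree}.
#' @export
loadCladeTree <- function(config = NULL, ref = rCRSAnnotation()) {
    if (is.null(config))
        config <- system.file("extdata", "clade_tree_n1a.yaml",
                              package = "mtN1a", mustWork = TRUE)
    y <- yaml::read_yaml(config)
    if (is.null(y$clades) || !length(y$clades))
        stop("clade config error: no clades defined")
    nearTol <- if (!is.null(y$near_tolerance)) as.numeric(y$near_tolerance)
               else 1
    nm <- names(y$clades)
    if (is.null(nm) || anyDuplicated(nm))
        stop("clade config error: clades must be uniquely named")
    parent <- vapply(y$clades, function(cl)
        if (is.null(cl$parent)) NA_character_ else as.character(cl$parent),
        character(1))
    cl <- data.frame(name = nm, parent = unname(parent),
                     stringsAsFactors = FALSE)
    if (sum(is.na(cl$parent)) != 1L)
        stop("clade config error: exactly one root required")
    if (any(!is.na(cl$parent) & !cl$parent %in% cl$name))
        stop("clade config error: orphan clade (unknown parent ",
             paste(setdiff(cl$parent, c(cl$name, NA)), collapse = ", "), ")")
    # depth by iterated parent lookup; non-convergence means a cycle
    depth <- rep(NA_integer_, nrow(cl))
    depth[is.na(cl$parent)] <- 0L
    for (it in seq_len(nrow(cl) + 1L)) {
        todo <- which(is.na(depth))
        if (!length(todo)) break
        for (i in todo) {
            pd <- depth[match(cl$parent[i], cl$name)]
            if (!is.na(pd)) depth[i] <- pd + 1L
        }
    }
    if (anyNA(depth))
        stop("clade config error: cycle involving ",
             paste(cl$name[is.na(depth)], collapse = ", "))
    cl$depth <- depth
    cl <- cl[order(cl$depth, cl$name), , drop = FALSE]
    rownames(cl) <- NULL

    levels <- lapply(cl$name, function(name) {
        spec <- y$clades[[name]]
        ent <- list()
        for (seg in c("hvs1", "hvs2", "coding")) {
            segName <- c(hvs1 = "HVS1", hvs2 = "HVS2", coding = "coding")[seg]
            for (tokset in list(c(key = seg, kind = "diag"),
                                c(key = paste0("anti_", seg), kind = "anti"))) {
                toks <- spec[[tokset["key"]]]
                if (is.null(toks)) next
                for (tok in as.character(toks)) {
                    isBack <- startsWith(tok, "@")
                    kind <- if (isBack) "back" else tokset["kind"]
                    call <- parseMotif(sub("^@", "", tok), segName, ref)
                    w <- 1
                    if (!is.null(spec$weights) &&
                        tok %in% names(spec$weights))
                        w <- as.numeric(spec$weights[[tok]])
                    ent[[length(ent) + 1L]] <- data.frame(
                        segment = segName, position = call$position,
                        derived = call$derived, event = call$event,
                        kind = kind, weight = w, token = tok,
                        stringsAsFactors = FALSE)
                }
            }
        }
        if (!length(ent))
            data.frame(segment = character(0), position = integer(0),
                       derived = character(0), event = character(0),
                       kind = character(0), weight = numeric(0),
                       token = character(0), stringsAsFactors = FALSE)
        else do.call(rbind, ent)
    })
    names(levels) <- cl$name
    nDiag <- vapply(levels[cl$name], base::nrow, 1L)
    emptyDef <- cl$name[cl$depth > 0L & nDiag == 0L]
    if (length(emptyDef))
        warning("clade(s) without any diagnostics: ",
                paste(emptyDef, collapse = ", "),
                " (matched purely through their parent's profile)")

    # accumulate root-to-clade profiles in depth order
    profiles <- list()
    for (i in seq_len(nrow(cl))) {
        name <- cl$name[i]
        prof <- if (is.na(cl$parent[i]))
            list(expect = data.frame(segment = character(0),
                                     position = integer(0),
                                     derived = character(0),
                                     event = character(0),
                                     weight = numeric(0),
                                     level = character(0),
                                     stringsAsFactors = FALSE),
                 backs = data.frame(segment = character(0),
                                    position = integer(0),
                                    ancDerived = character(0),
                                    weight = numeric(0), level = character(0),
                                    stringsAsFactors = FALSE),
                 antis = data.frame(segment = character(0),
                                    position = integer(0),
                                    weight = numeric(0), level = character(0),
                                    stringsAsFactors = FALSE))
        else profiles[[cl$parent[i]]]
        lv <- levels[[name]]
        for (j in seq_len(nrow(lv))) {
            e <- lv[j, ]
            if (e$kind == "diag") {
                k <- which(prof$expect$position == e$position)
                if (length(k) && any(prof$expect$derived[k] == e$derived))
                    stop("clade config error: diagnostic ", e$token,
                         " of ", name, " duplicates an ancestor's")
                if (length(k)) prof$expect <- prof$expect[-k, , drop = FALSE]
                prof$expect <- rbind(prof$expect, data.frame(
                    segment = e$segment, position = e$position,
                    derived = e$derived, event = e$event, weight = e$weight,
                    level = name, stringsAsFactors = FALSE))
            } else if (e$kind == "back") {
                k <- which(prof$expect$position == e$position)
                if (length(k)) {
                    prof$backs <- rbind(prof$backs, data.frame(
                        segment = e$segment, position = e$position,
                        ancDerived = prof$expect$derived[k[1]],
                        weight = e$weight, level = name,
                        stringsAsFactors = FALSE))
                    prof$expect <- prof$expect[-k, , drop = FALSE]
                } else {
                    warning("back-mutation diagnostic ", e$token, " of ",
                            name, " has no ancestral diagnostic; treated ",
                            "as an anti-diagnostic")
                    prof$antis <- rbind(prof$antis, data.frame(
                        segment = e$segment, position = e$position,
                        weight = e$weight, level = name,
                        stringsAsFactors = FALSE))
                }
            } else {
                prof$antis <- rbind(prof$antis, data.frame(
                    segment = e$segment, position = e$position,
                    weight = e$weight, level = name,
                    stringsAsFactors = FALSE))
            }
        }
        profiles[[name]] <- prof
    }

    new("HaplogroupTree", clades = cl, levels = levels, profiles = profiles,
        nearTolerance = nearTol)
}

#' Clade names of a haplogroup tree
#' @param tree a \linkS4class{HaplogroupTree}.
#' @return character vector in depth order (root first).
#' @export
cladeNames <- function(tree) tree@clades$name

#' Root clade name
#' @rdname cladeNames
#' @export
rootClade <- function(tree) tree@clades$name[tree@clades$depth == 0L]

#' Descendants of a clade (including itself)
#' @param tree a \linkS4class{HaplogroupTree}.
#' @param clade clade name.
#' @export
descendantClades <- function(tree, clade) {
    out <- clade
    repeat {
        kids <- tree@clades$name[!is.na(tree@clades$parent) &
                                 tree@clades$parent %in% out]
        new <- setdiff(kids, out)
        if (!length(new)) break
        out <- c(out, new)
    }
    out
}

#' Ancestors of a clade, root first (including itself)
#' @rdname descendantClades
#' @export
ancestorClades <- function(tree, clade) {
    path <- clade
    repeat {
        p <- tree@clades$parent[match(path[1], tree@clades$name)]
        if (is.na(p)) break
        path <- c(p, path)
    }
    path
}

setMethod("show", "HaplogroupTree", function(object) {
    cl <- object@clades
    cat("HaplogroupTree:", nrow(cl), "clades (root ",
        rootClade(object), "), max depth ", max(cl$depth), "\n", sep = "")
    for (i in seq_len(nrow(cl))) {
        lv <- object@levels[[cl$name[i]]]
        toks <- if (nrow(lv)) paste(ifelse(lv$kind == "anti",
                                           paste0("!", lv$token), lv$token),
                                    collapse = " ") else ""
        cat(strrep("  ", cl$depth[i] + 1L), cl$name[i],
            if (nzchar(toks)) paste0("  [", toks, "]") else "", "\n",
            sep = "")
    }
})
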