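#' Read a rooted tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces unique tip labels and
#' at least two tips. Trifurcating (unresolved) roots are accepted.
#'
#' @param path Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips")
  tree
}

#' Parsimony reconstruction of motif presence/absence on a tree
#'
#' Minimum-change (Fitch/Sankoff, unit cost, gains and losses weighted
#' equally) reconstruction of a binary presence/absence character. For every
#' node the full set of states occurring in *some* most-parsimonious
#' reconstruction is reported, so an ambiguous ancestor (e.g. "present in the
#' family ancestor and lost in one genus" vs "gained later and transferred")
#' shows up as a two-state set rather than being silently resolved.
#'
#' Implemented as a two-pass dynamic program over the two states: a postorder
#' pass computing the minimal subtree cost of each node-state assignment and
#' a preorder pass adding the cost of the rest of the tree, which handles
#' polytomies exactly.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named character vector, tip label -> `"present"` or
#'   `"absent"`, covering every tip.
#' @return An object of class `ancestral_states`: list with `min_changes`,
#'   `node_states` (list over nodes, tips first in `tree$tip.label` order,
#'   then internal nodes in `ape` numbering), and `root_states`.
#' @export
fitch_presence_absence <- function(tree, tip_states) {
  stopifnot(inherits(tree, "phylo"))
  states <- c("present", "absent")
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    stop("missing tip state(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(tip_states), states)
  if (length(bad)) stop("states must be 'present'/'absent', got: ",
                        paste(bad, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- ntip + 1L
  ## postorder: down[v, s] = min changes within subtree of v given state s
  down <- matrix(0, nrow = total, ncol = 2L)
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    down[i, ] <- ifelse(states == s, 0, Inf)
  }
  post <- rev(internal_preorder(tree))
  for (v in post) {
    for (s in 1:2) {
      down[v, s] <- sum(vapply(kids[[as.character(v)]], function(ch) {
        min(down[ch, s], down[ch, 3L - s] + 1)
      }, numeric(1)))
    }
  }
  min_changes <- min(down[root, ])
  ## preorder: up[v, s] = min changes outside subtree of v given v has state s
  up <- matrix(0, nrow = total, ncol = 2L)
  for (v in internal_preorder(tree)) {
    for (ch in kids[[as.character(v)]]) {
      sib <- setdiff(kids[[as.character(v)]], ch)
      sib_cost <- function(s) sum(vapply(sib, function(w) {
        min(down[w, s], down[w, 3L - s] + 1)
      }, numeric(1)))
      for (s in 1:2) {
        up[ch, s] <- min(up[v, 1L] + sib_cost(1L) + (s != 1L),
                         up[v, 2L] + sib_cost(2L) + (s != 2L))
      }
    }
  }
  node_states <- lapply(seq_len(total), function(v) {
    states[which(down[v, ] + up[v, ] == min_changes)]
  })
  labels <- c(tree$tip.label,
              tree$node.label %||% paste0("node", seq_len(nnode) + ntip))
  names(node_states) <- labels
  structure(list(min_changes = min_changes, node_states = node_states,
                 root_states = node_states[[root]]),
            class = "ancestral_states")
}

## internal nodes in preorder (parents before children)
internal_preorder <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  root <- ntip + 1L
  out <- integer(0)
  stack <- root
  kids <- split(edge[, 2L], edge[, 1L])
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    stack <- c(ch[ch > ntip], stack)
  }
  out
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states> min changes %d, root {%s}\n",
              x$min_changes, paste(x$root_states, collapse = ", ")))
  invisible(x)
}

#' Annotate a tree with per-species candidate motifs
#'
#' Joins an aggregated call table onto the tree tips and reconstructs each
#' motif's presence/absence history by parsimony. Tips absent from the calls
#' are marked `"no data"` and excluded from reconstructions; species present
#' in the calls but missing from the tree are reported with a warning.
#'
#' @param tree A rooted `phylo` object.
#' @param calls A `motif_calls` data.frame covering one or more species.
#' @return List with `tips` (`data.frame`: `tip`, `motifs`) and `ancestry`
#'   (`data.frame` per motif: `motif`, `min_changes`, `root_states`).
#' @export
annotate_tree <- function(tree, calls) {
  stopifnot(inherits(tree, "phylo"))
  orphans <- setdiff(unique(calls$species), tree$tip.label)
  if (length(orphans)) {
    warning("species in calls but not in tree: ",
            paste(orphans, collapse = ", "))
  }
  cand <- calls[calls$candidate, , drop = FALSE]
  tip_motifs <- vapply(tree$tip.label, function(tp) {
    if (!tp %in% calls$species) return("no data")
    m <- sort(unique(cand$motif[cand$species == tp]))
    if (length(m)) paste(m, collapse = ";") else "none"
  }, character(1))
  tips <- data.frame(tip = tree$tip.label, motifs = unname(tip_motifs),
                     stringsAsFactors = FALSE)
  motifs <- sort(unique(cand$motif))
  covered <- tree$tip.label[tree$tip.label %in% calls$species]
  ancestry <- if (length(motifs) && length(covered) >= 2L) {
    do.call(rbind, lapply(motifs, function(m) {
      st <- setNames(ifelse(covered %in% cand$species[cand$motif == m],
                            "present", "absent"), covered)
      sub <- if (length(covered) < length(tree$tip.label)) {
        ape::keep.tip(tree, covered)
      } else tree
      anc <- fitch_presence_absence(sub, st)
      data.frame(motif = m, min_changes = anc$min_changes,
                 root_states = paste(anc$root_states, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(motif = character(), min_changes = integer(),
               root_states = character(), stringsAsFactors = FALSE)
  }
  rownames(ancestry) <- NULL
  list(tips = tips, ancestry = ancestry)
}
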