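#' Build the mutation-by-sample frequency matrix of one patient
#'
#' Rows are the patient's validated mutations, columns the plaque samples
#' ordered by segment start along the plaque axis, cells the clonal cell
#' frequency (0 where the mutation is absent or below the detection floor).
#'
#' @param mutations a [quantify_mutations()] table.
#' @param meta sample metadata.
#' @param patient patient id to map.
#' @return numeric matrix of class `mutation_matrix`, with the segment
#'   geometry `data.frame` attached as attribute `"geometry"`.
#' @export
build_matrix <- function(mutations, meta, patient) {
  check_meta(meta)
  geom <- meta[meta$patient == patient & meta$tissue_class == "plaque", ,
               drop = FALSE]
  stop_if(nrow(geom) == 0, "patient ", patient, " has no plaque samples")
  stop_if(anyNA(geom$start_mm),
          "plaque sample without segment geometry for patient ", patient)
  geom <- geom[order(geom$start_mm), , drop = FALSE]
  mm <- mutations[mutations$patient == patient &
                    mutations$sample_id %in% geom$sample_id, , drop = FALSE]
  keys <- unique(variant_key(mm$chrom, mm$pos, mm$ref, mm$alt))
  m <- matrix(0, nrow = length(keys), ncol = nrow(geom),
              dimnames = list(keys, geom$sample_id))
  if (nrow(mm) > 0) {
    mk <- variant_key(mm$chrom, mm$pos, mm$ref, mm$alt)
    m[cbind(match(mk, keys), match(mm$sample_id, geom$sample_id))] <-
      ifelse(mm$detected, mm$ccf, 0)
  }
  structure(m, geometry = geom[, c("sample_id", "start_mm", "end_mm")],
            class = c("mutation_matrix", class(m)))
}

#' Physical extent bounds of a clone from its positive segments
#'
#' A clone detected in several disjoint segments must physically bridge the
#' unsequenced gaps between them. The lower bound is the distance between
#' the nearest edges of the outermost positive segments (0 for a single
#' segment); the upper-consistent bound is the distance between their
#' farthest edges.
#'
#' @param positive logical or numeric vector over samples (in geometry
#'   order); nonzero entries mark detection.
#' @param geometry `data.frame` with `start_mm`, `end_mm` per sample, in the
#'   same order.
#' @return named numeric vector `c(extent_lower_mm, extent_upper_mm)`.
#' @export
#' @examples
#' g <- data.frame(start_mm = c(0, 6), end_mm = c(2, 8))
#' clone_extent(c(TRUE, TRUE), g)  # lower 4, upper 8
clone_extent <- function(positive, geometry) {
  pos <- which(as.numeric(positive) > 0)
  stop_if(length(pos) == 0, "clone_extent needs at least one positive sample")
  stop_if(length(positive) != nrow(geometry),
          "'positive' and 'geometry' lengths differ")
  first <- pos[1]; last <- pos[length(pos)]
  c(extent_lower_mm = max(0, geometry$start_mm[last] - geometry$end_mm[first]),
    extent_upper_mm = geometry$end_mm[last] - geometry$start_mm[first])
}

# pairwise linkability under the grouping rule; exported pieces operate on a
# mutation_matrix so the rule stays testable against a brute-force oracle
linkable_pair <- function(f1, f2, rel_tol, gap_tolerant = FALSE) {
  p1 <- f1 > 0; p2 <- f2 > 0
  if (!any(p1) || !any(p2)) return(FALSE)
  if (!identical(p1, p2)) {
    if (!gap_tolerant) return(FALSE)
    diffc <- which(xor(p1, p2))
    if (length(diffc) != 1L) return(FALSE)
    un <- which(p1 | p2)
    # the single mismatching column must be interior to the union span
    if (diffc <= un[1] || diffc >= un[length(un)]) return(FALSE)
  }
  shared <- which(p1 & p2)
  if (length(shared) == 0L) return(FALSE)
  rel <- abs(f1[shared] - f2[shared]) / pmax(f1[shared], f2[shared])
  all(rel <= rel_tol)
}

#' Group mutations into putative clones
#'
#' Two mutations are linkable when (i) they are detected in exactly the same
#' samples and (ii) in every shared positive sample their clonal cell
#' frequencies differ by at most `rel_tol` relative to the larger one
#' (mutations travelling in one clone show similar magnitudes and similar
#' intersample differences). Putative clones are the connected components of
#' the linkable relation, so the result is deterministic and invariant to
#' row order. The optional gap-tolerant mode additionally links mutations
#' whose presence patterns differ in a single interior sample (tolerating
#' one sampling dropout); it is off by default. Groupings are hypotheses
#' about co-travelling mutations, not ground truth.
#'
#' @param m a [build_matrix()] result (or plain matrix of frequencies).
#' @param rel_tol relative-difference tolerance in `(0, 1]` (default 0.5).
#' @param gap_tolerant allow one interior presence mismatch (default
#'   `FALSE`).
#' @return object of class `clone_groups`: list with `membership` (integer
#'   group per mutation), `groups` (per-group summary incl. extent bounds
#'   when geometry is available) and `profiles` (column-wise median
#'   frequency profile per group).
#' @export
group_into_clones <- function(m, rel_tol = 0.5, gap_tolerant = FALSE) {
  stop_if(!is.matrix(m), "'m' must be a mutation matrix")
  stop_if(rel_tol <= 0 || rel_tol > 1, "'rel_tol' must lie in (0, 1]")
  n <- nrow(m)
  geom <- attr(m, "geometry")
  if (n == 0)
    return(structure(list(membership = setNames(integer(0), character(0)),
                          groups = data.frame(), profiles = m),
                     class = "clone_groups"))
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (linkable_pair(m[i, ], m[j, ], rel_tol, gap_tolerant)) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  # connected components by breadth-first search
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  membership <- setNames(comp, rownames(m))
  profiles <- do.call(rbind, lapply(seq_len(cur), function(g) {
    apply(m[comp == g, , drop = FALSE], 2, median)
  }))
  rownames(profiles) <- paste0("clone_", seq_len(cur))
  groups <- do.call(rbind, lapply(seq_len(cur), function(g) {
    members <- rownames(m)[comp == g]
    ext <- if (!is.null(geom) && any(profiles[g, ] > 0))
      clone_extent(profiles[g, ], geom) else
      c(extent_lower_mm = NA_real_, extent_upper_mm = NA_real_)
    data.frame(group = g, n_members = length(members),
               members = paste(members, collapse = ";"),
               extent_lower_mm = ext[["extent_lower_mm"]],
               extent_upper_mm = ext[["extent_upper_mm"]])
  }))
  structure(list(membership = membership, groups = groups,
                 profiles = profiles),
            class = "clone_groups")
}

#' @export
print.clone_groups <- function(x, ...) {
  cat("Putative clone groups: ", nrow(x$groups), " group(s) over ",
      length(x$membership), " mutation(s)\n", sep = "")
  if (nrow(x$groups)) {
    show <- x$groups
    show$members <- ifelse(nchar(show$members) > 40,
                           paste0(substr(show$members, 1, 37), "..."),
                           show$members)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Flag samples whose summed frequencies imply multi-mutation clones
#'
#' If the clonal cell frequencies of a sample's mutations summed over
#' mutations exceed 100%, the mutations cannot all sit in distinct cells:
#' at least some clones must carry more than one mutation.
#'
#' @param m a [build_matrix()] result.
#' @return named logical vector over samples (`TRUE` = frequency sum > 1).
#' @export
flag_multimutation_samples <- function(m) {
  stop_if(!is.matrix(m), "'m' must be a mutation matrix")
  colSums(m) > 1
}
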