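# Convert an ordered, oriented element list into a minimal-depth
# alternating alpha/omega assembly tree, and simulate the plan end-to-end
# through the one-pot reaction model.

# Chunk m constructs left-to-right into groups of <= 3. A remainder of 1 is
# rebalanced to ...,2,2 so no internal level carries a singleton transfer.
chunk_sizes <- function(m) {
  if (m <= 3L) return(m)
  k <- m %/% 3L
  r <- m %% 3L
  if (r == 0L) rep(3L, k)
  else if (r == 2L) c(rep(3L, k), 2L)
  else c(rep(3L, k - 1L), 2L, 2L)
}

#' Plan a multi-round assembly
#'
#' Builds a depth-optimal plan that joins `n` ordered, oriented elements
#' into a single insert: level 1 transfers each element from the library
#' into a member of `first_family`; each subsequent level combines
#' consecutive constructs, three at a time (members 1A+B+C) or two at a
#' time (1A+2), alternating family, until one construct remains. The total
#' number of cloning rounds is `1 + ceiling(log3(n))` for n >= 2 and 1 for
#' a single element. Antisense elements are assigned the R variant of
#' their member at level 1.
#'
#' @param elements Character vector of element ids (sense), or a
#'   data.frame/tibble with columns `id` and `orientation`
#'   ("sense"/"antisense").
#' @param first_family `"alpha"` or `"omega"`.
#' @param final_destination Optional: `"pSTART"` to make the final
#'   construct a library entry, otherwise the 1A member of the final
#'   family.
#' @return A `tnt_plan` object.
#' @export
plan_assembly <- function(elements, first_family = c("alpha", "omega"),
                          final_destination = NULL) {
  first_family <- match.arg(first_family)
  if (is.character(elements)) {
    elements <- tibble::tibble(id = elements, orientation = "sense")
  }
  elements <- tibble::as_tibble(elements)
  if (!"orientation" %in% names(elements)) elements$orientation <- "sense"
  n <- nrow(elements)
  if (n < 1L) stop("need at least one element", call. = FALSE)
  if (anyDuplicated(elements$id)) {
    stop("element ids must be unique within one plan request", call. = FALSE)
  }
  if (!all(elements$orientation %in% c("sense", "antisense"))) {
    stop("orientation must be 'sense' or 'antisense'", call. = FALSE)
  }

  fam_at <- function(level) {
    if (level %% 2L == 1L) first_family
    else setdiff(c("alpha", "omega"), first_family)
  }

  # bottom-up grouping: children[[level]][[i]] = indices (into level-1
  # nodes) grouped into node i of that level
  n_per_level <- list(n)
  grouping <- list(NULL)
  m <- n
  level <- 1L
  while (m > 1L) {
    sizes <- chunk_sizes(m)
    idx <- split(seq_len(m), rep(seq_along(sizes), sizes))
    level <- level + 1L
    grouping[[level]] <- idx
    m <- length(sizes)
    n_per_level[[level]] <- m
  }
  total_steps <- level

  # top-down variant assignment
  variants <- vector("list", total_steps)
  variants[[total_steps]] <- "1A"
  if (total_steps > 1L) {
    for (lv in total_steps:2L) {
      kids <- grouping[[lv]]
      vlow <- character(n_per_level[[lv - 1L]])
      for (gi in seq_along(kids)) {
        ks <- kids[[gi]]
        vs <- switch(as.character(length(ks)),
                     "1" = "1A", "2" = c("1A", "2"), "3" = c("1A", "B", "C"))
        vlow[ks] <- vs
      }
      variants[[lv - 1L]] <- vlow
    }
  }

  node_ref <- function(level, i) sprintf("N%d.%d", level, i)
  member_of <- function(level, i, antisense = FALSE) {
    v <- variants[[level]][i]
    paste0(fam_at(level), v, if (antisense) "-R" else "")
  }

  steps <- list()
  for (i in seq_len(n)) {
    anti <- elements$orientation[i] == "antisense"
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, level = 1L,
      destination = member_of(1L, i, anti),
      inputs = list(paste0("element:", elements$id[i])),
      output = node_ref(1L, i))
  }
  if (total_steps > 1L) {
    for (lv in 2L:total_steps) {
      kids <- grouping[[lv]]
      for (gi in seq_along(kids)) {
        dest <- if (lv == total_steps && identical(final_destination,
                                                   "pSTART")) {
          "pSTART"
        } else {
          member_of(lv, gi)
        }
        steps[[length(steps) + 1L]] <- tibble::tibble(
          step = length(steps) + 1L, level = lv, destination = dest,
          inputs = list(node_ref(lv - 1L, kids[[gi]])),
          output = node_ref(lv, gi))
      }
    }
  }
  steps <- dplyr::bind_rows(steps)
  leaf_members <- vapply(seq_len(n), function(i)
    member_of(1L, i, elements$orientation[i] == "antisense"), character(1))
  structure(
    list(steps = steps,
         elements = tibble::tibble(id = elements$id,
                                   orientation = elements$orientation,
                                   node = vapply(seq_len(n), node_ref,
                                                 character(1), level = 1L),
                                   member = leaf_members),
         total_steps = total_steps,
         first_family = first_family,
         final_family = if (identical(final_destination, "pSTART")) "entry"
         else fam_at(total_steps),
         final_destination = if (is.null(final_destination))
           paste0(fam_at(total_steps), "1A") else final_destination),
    class = "tnt_plan")
}

#' @export
print.tnt_plan <- function(x, ...) {
  cat(sprintf("<tnt_plan> %d element(s), %d cloning round(s), final: %s\n",
              nrow(x$elements), x$total_steps, x$final_destination))
  lv <- x$steps$level
  for (l in unique(lv)) {
    cat(sprintf("  round %d: %d reaction(s) into %s\n", l, sum(lv == l),
                paste(unique(x$steps$destination[lv == l]), collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tnt_plan <- function(x, ...) {
  out <- x$steps
  out$inputs <- vapply(out$inputs, paste, character(1), collapse = " + ")
  out
}

#' @export
glance.tnt_plan <- function(x, ...) {
  sz <- vapply(x$steps$inputs, length, integer(1))
  tibble::tibble(
    n_elements = nrow(x$elements),
    total_steps = x$total_steps,
    n_reactions = nrow(x$steps),
    n_binary = sum(sz == 2L & x$steps$level > 1L),
    n_ternary = sum(sz == 3L & x$steps$level > 1L),
    first_family = x$first_family,
    final_family = x$final_family)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an assembly plan
#'
#' Shows the assembly tree: one point per reaction, positioned by cloning
#' round (y) and output position (x), coloured by destination family.
#'
#' @param object A `tnt_plan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnt_plan <- function(object, ...) {
  st <- tidy(object)
  st$position <- as.numeric(sub("^N\\d+\\.", "", st$output))
  st$family <- sub("^(alpha|omega|pSTART).*$", "\\1", st$destination)
  # spread positions so levels centre above their inputs
  st <- dplyr::group_by(st, .data$level)
  st <- dplyr::mutate(st, x = (.data$position - 0.5) /
                        max(.data$position))
  st <- dplyr::ungroup(st)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$level,
                                   colour = .data$family)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$destination),
                       vjust = -1, size = 2.7, show.legend = FALSE) +
    ggplot2::scale_y_continuous(breaks = seq_len(object$total_steps)) +
    ggplot2::labs(x = NULL, y = "cloning round", colour = "family") +
    ggplot2::theme_minimal()
}

# -- simulation --------------------------------------------------------------

#' Simulate an assembly plan end-to-end
#'
#' Executes every step of the plan through the one-pot reaction model with
#' the correct enzyme per destination family, carrying methylation state
#' (alpha destinations are used in their M.TaqI-methylated form; every
#' product is then propagated in a non-methylating strain, erasing marks
#' before the next round). Aborts if any step yields anything other than
#' exactly one stable productive product.
#'
#' @param plan A `tnt_plan`.
#' @param element_library Named list of `tnt_dna` elements (ids matching
#'   the plan), or the result of [random_element_library()].
#' @param registry Registry tibble from [build_registry()].
#' @param backbone_length Backbone filler length used for the synthetic
#'   vectors.
#' @param cache Optional environment reused across calls to share the
#'   synthesised member plasmids and entry clones (batch simulations).
#' @return List with `construct` (final `tnt_dna`), `provenance` (tibble
#'   id/orientation in final left-to-right order), and `constructs` (all
#'   intermediate molecules).
#' @export
simulate_plan <- function(plan, element_library,
                          registry = build_registry(),
                          backbone_length = 300L, cache = NULL) {
  if (!inherits(plan, "tnt_plan")) stop("plan must be a tnt_plan",
                                        call. = FALSE)
  lib <- element_library
  if (!is.null(lib$molecules)) lib <- lib$molecules
  member_cache <- cache %||% new.env(parent = emptyenv())
  get_member <- function(name) {
    key <- paste0("member:", name)
    if (!is.null(member_cache[[key]])) return(member_cache[[key]])
    mol <- make_member_plasmid(name, registry,
                               backbone_length = backbone_length)
    member_cache[[key]] <- mol
    mol
  }
  constructs <- list()
  resolve <- function(ref) {
    if (startsWith(ref, "element:")) {
      id <- sub("^element:", "", ref)
      key <- paste0("entry:", id)
      if (!is.null(member_cache[[key]])) return(member_cache[[key]])
      el <- lib[[id]]
      if (is.null(el)) stop("element not in library: ", id, call. = FALSE)
      clone <- make_entry_clone(el, registry,
                                backbone_length = backbone_length)
      member_cache[[key]] <- clone
      return(clone)
    }
    out <- constructs[[ref]]
    if (is.null(out)) stop("unresolved construct reference: ", ref,
                           call. = FALSE)
    out
  }
  for (si in seq_len(nrow(plan$steps))) {
    st <- plan$steps[si, ]
    dest_name <- st$destination
    # a level-1 transfer is fully determined by (element, destination):
    # reuse its product across plans sharing the cache
    step_key <- if (st$level == 1L) {
      paste0("transfer:", dest_name, "|", st$inputs[[1]][1])
    } else NULL
    if (!is.null(step_key) && !is.null(member_cache[[step_key]])) {
      out <- member_cache[[step_key]]
      out$id <- st$output
      constructs[[st$output]] <- out
      next
    }
    inputs <- lapply(st$inputs[[1]], resolve)
    dest <- get_member(dest_name)
    dest_row <- registry_member(registry, dest_name)
    enzyme <- if (dest_row$family == "alpha") "EarI"
    else if (dest_row$family == "omega") "LguI"
    else { # pSTART destination: use the input family's release enzyme
      in_fam <- if (st$level %% 2L == 1L) plan$first_family
      else setdiff(c("alpha", "omega"), plan$first_family)
      # inputs are at level - 1
      in_fam <- {
        lvl_in <- st$level - 1L
        if (lvl_in < 1L) plan$first_family
        else if (lvl_in %% 2L == 1L) plan$first_family
        else setdiff(c("alpha", "omega"), plan$first_family)
      }
      if (in_fam == "alpha") "LguI" else "EarI"
    }
    pot <- one_pot(c(inputs, list(dest)), enzyme)
    cand <- Filter(function(p) {
      bb <- p$molecule$features
      any(bb$type == "backbone" & bb$label == dest_name) &&
        !any(bb$type == "stuffer")
    }, pot$products)
    if (length(cand) != 1L) {
      stop(sprintf(
        "step %d (%s <- %s): expected exactly 1 stable productive product, got %d; dangling junction(s): %s",
        st$step, dest_name, paste(st$inputs[[1]], collapse = " + "),
        length(cand),
        if (length(pot$dangling)) paste(pot$dangling, collapse = ", ")
        else "none"), call. = FALSE)
    }
    out <- cand[[1]]$molecule
    out <- erase_marks(out) # propagation in a non-methylating strain
    if (!is.null(step_key)) member_cache[[step_key]] <- out
    out$id <- st$output
    constructs[[st$output]] <- out
  }
  final <- constructs[[plan$steps$output[nrow(plan$steps)]]]
  list(construct = final,
       provenance = product_provenance(final),
       constructs = constructs)
}

# Elements of a (circular) construct in left-to-right order downstream of
# the backbone, normalised so the backbone reads on the plus strand.
product_provenance <- function(mol) {
  bb <- mol$features[mol$features$type == "backbone", , drop = FALSE]
  if (nrow(bb)) {
    if (bb$strand[1] == "-") {
      mol <- reverse_complement_molecule(mol)
      bb <- mol$features[mol$features$type == "backbone", , drop = FALSE]
    }
    if (is_circular(mol)) mol <- rotate_molecule(mol, bb$start[1])
  }
  el <- mol$features[mol$features$type == "element", , drop = FALSE]
  el <- el[order(el$start), , drop = FALSE]
  tibble::tibble(id = el$label,
                 orientation = ifelse(el$strand == "+", "sense",
                                      "antisense"),
                 start = el$start, end = el$end)
}

#' Predicted insert sizes along a plan
#'
#' Computes, without sequence-level simulation, the released-insert span of
#' every construct in the plan and the final insert size, from element
#' lengths plus the 3-nt junction bookkeeping of the member geometry.
#' Spans count each junction 3-mer once; joining k inserts merges k-1
#' shared junctions.
#'
#' @param plan A `tnt_plan`.
#' @param element_library Named list of elements or
#'   [random_element_library()] result.
#' @param registry Registry tibble.
#' @return Tibble with per-node `insert_span` (content between the accept
#'   junctions, inclusive) and `release_span` (the fragment released for
#'   the next round).
#' @export
insert_size <- function(plan, element_library, registry = build_registry()) {
  lib <- element_library
  if (!is.null(lib$molecules)) lib <- lib$molecules
  extras <- function(member_name) {
    m <- registry_member(registry, member_name)
    if (m$family == "entry") return(0L)
    is_r <- m$release_orientation == "antisense"
    left_extra <- if (is_r || m$release_left != "s1") 3L else 0L
    right_extra <- if (is_r || m$release_right != "s2") 3L else 0L
    left_extra + right_extra
  }
  spans <- list()
  rows <- list()
  for (si in seq_len(nrow(plan$steps))) {
    st <- plan$steps[si, ]
    ins <- st$inputs[[1]]
    if (st$level == 1L) {
      id <- sub("^element:", "", ins)
      el <- lib[[id]]
      if (is.null(el)) stop("element not in library: ", id, call. = FALSE)
      stored <- dna_length(el) + 6L
    } else {
      child_rel <- vapply(ins, function(r) spans[[r]], numeric(1))
      stored <- sum(child_rel) - 3L * (length(ins) - 1L)
    }
    release <- if (st$destination == "pSTART") stored + 0L
    else stored + extras(st$destination)
    spans[[st$output]] <- release
    rows[[si]] <- tibble::tibble(
      node = st$output, level = st$level, member = st$destination,
      n_inputs = length(ins), insert_span = stored,
      release_span = release)
  }
  dplyr::bind_rows(rows)
}
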