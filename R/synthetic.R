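# Seeded generator of valid reference lineages and an error injector that
# corrupts a reference into a computed result with known expected error
# counts.  Together they form the self-contained test surface: no downloaded
# data is ever needed to exercise the full comparison pipeline.

#' Parameters of the synthetic lineage generator
#'
#' Cells are axis-aligned squares (cubes in 3-D) of half-width `radius`
#' performing an integer random walk; per frame and per cell a division or a
#' disappearance may fire, and new cells may enter the field of view.  The
#' generator guarantees that markers within a frame never overlap by keeping
#' cell centres separated by more than `2 * radius + min_gap` in Chebyshev
#' distance.
#'
#' Defaults emulate a desk-scale fluorescence-nuclei-like series: 20 frames of
#' 128 x 128 pixels, 8 starting cells of half-width 2, a 2 % division chance,
#' 1 % disappearance chance and 2 % appearance chance per frame, and steps of
#' at most 3 pixels per axis.
#'
#' @param n_frames Number of frames.
#' @param shape Image dimensions (length 2 or 3).
#' @param n_initial Number of cells in frame 0.
#' @param radius Marker half-width in pixels (side is `2 * radius + 1`).
#' @param p_divide,p_disappear Per-cell, per-frame event probabilities.
#' @param p_appear Per-frame probability that one new cell enters.
#' @param max_step Largest per-axis displacement of the random walk.
#' @param min_gap Minimum empty margin between markers, in pixels.
#' @param seed Integer seed; identical parameters give identical results.
#' @return An object of class `lineage_params`.
#' @export
lineage_params <- function(n_frames = 20L, shape = c(128L, 128L),
                           n_initial = 8L, radius = 2L, p_divide = 0.02,
                           p_disappear = 0.01, p_appear = 0.02,
                           max_step = 3L, min_gap = 1L, seed = 1L) {
  probs <- c(p_divide, p_disappear, p_appear)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (radius < 1) stop("'radius' must be >= 1")
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  if (!length(shape) %in% c(2L, 3L)) stop("'shape' must have length 2 or 3")
  if (any(shape < 2 * radius + 1))
    stop("image shape too small for the marker radius")
  if (max_step < 0 || min_gap < 0) stop("'max_step'/'min_gap' must be >= 0")
  structure(list(n_frames = as.integer(n_frames), shape = as.integer(shape),
                 n_initial = as.integer(n_initial), radius = as.integer(radius),
                 p_divide = p_divide, p_disappear = p_disappear,
                 p_appear = p_appear, max_step = as.integer(max_step),
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "lineage_params")
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

square_pixels <- function(center, radius) {
  as.matrix(expand.grid(lapply(center, function(c)
    (c - radius):(c + radius))))
}

# Disjointness-with-margin predicate on cell centres (Chebyshev distance).
position_ok <- function(pos, others, radius, min_gap, lo, hi) {
  if (any(pos < lo) || any(pos > hi)) return(FALSE)
  sep <- 2L * radius + min_gap
  for (o in others)
    if (max(abs(pos - o)) <= sep) return(FALSE)
  TRUE
}

#' Generate a synthetic reference lineage
#'
#' Simulates the cell events a tracking benchmark must represent: migration
#' (random walk), division (mother track ends, two daughter tracks start with
#' parent links), death or exit (track simply terminates), and entry (a new
#' parentless track appears).  Reappearance after a temporal gap is not
#' generated.  The output is always a valid [tracking_result()] and is fully
#' determined by `params` (including its seed).
#'
#' @param params A [lineage_params()] object.
#' @return A [tracking_result()].
#' @examples
#' ref <- generate_reference(lineage_params(n_frames = 6, n_initial = 3))
#' @export
generate_reference <- function(params) {
  stopifnot(inherits(params, "lineage_params"))
  with_seed(params$seed, generate_reference_impl(params))
}

generate_reference_impl <- function(p) {
  d <- length(p$shape)
  lo <- rep(p$radius + 1L, d)
  hi <- p$shape - p$radius
  tracks <- list()   # label -> list(label, t_init, t_end, parent)
  markers <- list()
  next_label <- 1L
  alive <- list()    # label (character) -> centre

  start_track <- function(frame, parent) {
    lab <- next_label
    next_label <<- next_label + 1L
    tracks[[as.character(lab)]] <<- list(label = lab, t_init = frame,
                                         t_end = NA_integer_,
                                         parent = parent)
    lab
  }
  end_track <- function(lab, frame)
    tracks[[as.character(lab)]]$t_end <<- frame
  record <- function(lab, frame, pos)
    markers[[length(markers) + 1L]] <<- marker(lab, frame,
                                               square_pixels(pos, p$radius))
  place_free <- function(existing, tries) {
    for (i in seq_len(tries)) {
      pos <- vapply(seq_len(d), function(j)
        sample(lo[j]:hi[j], 1L), 0L)
      if (position_ok(pos, existing, p$radius, p$min_gap, lo, hi))
        return(pos)
    }
    NULL
  }

  for (i in seq_len(p$n_initial)) {
    pos <- place_free(alive, 200L)
    if (is.null(pos))
      stop("could not place ", p$n_initial, " initial cells; ",
           "reduce the density or enlarge the image")
    lab <- start_track(0L, NA_integer_)
    alive[[as.character(lab)]] <- pos
    record(lab, 0L, pos)
  }

  daughter_offsets <- function() {
    # opposite displacements along a random axis/diagonal, far enough apart
    o <- 2L * p$radius + p$min_gap + 1L
    dirs <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), d)))
    dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
    dirs[sample(nrow(dirs)), , drop = FALSE] * o
  }

  if (p$n_frames > 1L) for (t in 1:(p$n_frames - 1L)) {
    placed <- list()
    new_alive <- list()
    labs <- as.character(sort(as.integer(names(alive))))
    for (k in seq_along(labs)) {
      lab <- labs[k]
      pos <- alive[[lab]]
      pending <- if (k < length(labs)) alive[labs[(k + 1L):length(labs)]]
      else list()
      obstacles <- c(placed, pending)
      u <- stats::runif(1L)
      if (u < p$p_disappear) {
        end_track(as.integer(lab), t - 1L)
        next
      }
      divided <- FALSE
      if (u < p$p_disappear + p$p_divide) {
        # one daughter inherits the mother's position, the other buds off;
        # this stays feasible next to the image border
        for (off in seq_len(nrow(dd <- daughter_offsets()))) {
          c1 <- pos
          c2 <- pos + dd[off, ]
          if (position_ok(c1, obstacles, p$radius, p$min_gap, lo, hi) &&
              position_ok(c2, c(obstacles, list(c1)), p$radius, p$min_gap,
                          lo, hi)) {
            end_track(as.integer(lab), t - 1L)
            for (cc in list(c1, c2)) {
              ch <- start_track(t, as.integer(lab))
              new_alive[[as.character(ch)]] <- cc
              placed[[length(placed) + 1L]] <- cc
              record(ch, t, cc)
            }
            divided <- TRUE
            break
          }
        }
      }
      if (divided) next
      moved <- NULL
      for (try in seq_len(20L)) {
        cand <- pos + sample((-p$max_step):p$max_step, d, replace = TRUE)
        if (position_ok(cand, obstacles, p$radius, p$min_gap, lo, hi)) {
          moved <- cand
          break
        }
      }
      if (is.null(moved) &&
          position_ok(pos, obstacles, p$radius, p$min_gap, lo, hi))
        moved <- pos
      if (is.null(moved)) {          # fully boxed in: treat as exit
        end_track(as.integer(lab), t - 1L)
        next
      }
      new_alive[[lab]] <- moved
      placed[[length(placed) + 1L]] <- moved
      record(as.integer(lab), t, moved)
    }
    if (stats::runif(1L) < p$p_appear) {
      pos <- place_free(placed, 30L)
      if (!is.null(pos)) {
        lab <- start_track(t, NA_integer_)
        new_alive[[as.character(lab)]] <- pos
        record(lab, t, pos)
      }
    }
    alive <- new_alive
  }
  for (lab in names(alive)) end_track(as.integer(lab), p$n_frames - 1L)

  tr <- do.call(rbind, lapply(tracks, function(x)
    data.frame(label = x$label, t_init = x$t_init, t_end = x$t_end,
               parent = x$parent)))
  tracking_result(p$n_frames, tr, markers)
}

# ---------------------------------------------------------------------------
# Edit scripts

new_edit <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "aogm_edit")
}

#' Edits of an error-injection script
#'
#' Each edit corrupts a reference result in a way that maps one-to-one onto a
#' tracking error type and carries an exactly predictable count delta
#' (enumerated from the error definitions on the edit's neighbourhood):
#'
#' * `edit_delete_vertex(label, frame)` removes one marker; the remainder of
#'   the track continues as a new parentless track.  Delta: FN+1 and EA+k,
#'   with k the number of reference edges incident to the removed marker.
#' * `edit_add_spurious(frame, center, radius)` inserts a square marker
#'   overlapping nothing.  Delta: FP+1.
#' * `edit_merge(label_a, label_b)` fuses two parallel tracks with identical
#'   spans (and no parents or children) into one track of union markers over
#'   all f frames of the span.  Delta: NS+f and EA+2(f-1), because every
#'   reference edge incident to a merged marker loses its counterpart when
#'   the non-split vertices are excluded from the induced subgraph.
#' * `edit_cut_edge(label, frame)` removes the track link between `frame` and
#'   `frame + 1`; the tail becomes a new parentless track.  Delta: EA+1.
#' * `edit_add_false_edge(child, parent)` invents a parent link onto a track
#'   that has none.  Delta: ED+1.
#' * `edit_flip_semantics(mother)` lets one daughter continue the mother's
#'   label so the division edge becomes a track link; the other daughters
#'   lose their parent links.  Delta: EC+1 and EA+(children-1).
#'
#' @param label,frame,center,radius,label_a,label_b,child,parent,mother Edit
#'   site coordinates; see above.
#' @return An object of class `aogm_edit`.
#' @name edit_script_edits
NULL

#' @rdname edit_script_edits
#' @export
edit_delete_vertex <- function(label, frame)
  new_edit("delete_vertex", label = as.integer(label),
           frame = as.integer(frame))

#' @rdname edit_script_edits
#' @export
edit_add_spurious <- function(frame, center, radius = 1L)
  new_edit("add_spurious", frame = as.integer(frame),
           center = as.integer(center), radius = as.integer(radius))

#' @rdname edit_script_edits
#' @export
edit_merge <- function(label_a, label_b)
  new_edit("merge", label_a = as.integer(label_a),
           label_b = as.integer(label_b))

#' @rdname edit_script_edits
#' @export
edit_cut_edge <- function(label, frame)
  new_edit("cut_edge", label = as.integer(label), frame = as.integer(frame))

#' @rdname edit_script_edits
#' @export
edit_add_false_edge <- function(child, parent)
  new_edit("add_false_edge", child = as.integer(child),
           parent = as.integer(parent))

#' @rdname edit_script_edits
#' @export
edit_flip_semantics <- function(mother)
  new_edit("flip_semantics", mother = as.integer(mother))

#' Bundle edits into a script
#'
#' @param ... `aogm_edit` objects (or a single list of them).
#' @return An object of class `edit_script`.
#' @seealso [edit_script_edits], [inject_errors()]
#' @export
edit_script <- function(...) {
  edits <- list(...)
  if (length(edits) == 1L && !inherits(edits[[1L]], "aogm_edit"))
    edits <- edits[[1L]]
  if (!all(vapply(edits, inherits, TRUE, "aogm_edit")))
    stop("all script entries must be aogm_edit objects")
  structure(list(edits = edits), class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  cat("<edit_script>", length(x$edits), "edit(s):",
      paste(vapply(x$edits, function(e) e$type, ""), collapse = ", "), "\n")
  invisible(x)
}

track_row <- function(ref, label) {
  i <- match(label, ref$tracks$label)
  if (is.na(i)) stop("script error: no track with label ", label)
  ref$tracks[i, ]
}

children_of <- function(ref, label)
  ref$tracks$label[!is.na(ref$tracks$parent) & ref$tracks$parent == label]

# Reference edges incident to the marker of `label` in `frame`.
ref_degree <- function(ref_graph, key)
  sum(ref_graph$edges$from == key | ref_graph$edges$to == key)

# Marker keys an edit touches; disjoint sites guarantee additive deltas.
edit_site <- function(edit, ref, ref_graph) {
  switch(edit$type,
    delete_vertex = {
      key <- marker_key(edit$label, edit$frame)
      e <- ref_graph$edges
      unique(c(key, e$to[e$from == key], e$from[e$to == key]))
    },
    add_spurious = character(),
    merge = {
      a <- track_row(ref, edit$label_a)
      b <- track_row(ref, edit$label_b)
      c(marker_key(a$label, a$t_init:a$t_end),
        marker_key(b$label, b$t_init:b$t_end))
    },
    cut_edge = marker_key(edit$label, c(edit$frame, edit$frame + 1L)),
    add_false_edge = {
      pr <- track_row(ref, edit$parent)
      ch <- track_row(ref, edit$child)
      c(marker_key(pr$label, pr$t_end), marker_key(ch$label, ch$t_init))
    },
    flip_semantics = {
      mo <- track_row(ref, edit$mother)
      kids <- ref$tracks[!is.na(ref$tracks$parent) &
                           ref$tracks$parent == edit$mother, ]
      c(marker_key(mo$label, mo$t_end),
        marker_key(kids$label, kids$t_init))
    },
    stop("unknown edit type: ", edit$type))
}

check_edit <- function(edit, ref, ref_graph) {
  switch(edit$type,
    delete_vertex = {
      tr <- track_row(ref, edit$label)
      if (edit$frame < tr$t_init || edit$frame > tr$t_end)
        stop("script error: track ", edit$label, " has no frame ",
             edit$frame)
    },
    add_spurious = {
      if (edit$frame < 0 || edit$frame > ref$n_frames - 1L)
        stop("script error: spurious frame out of range")
      px <- pixel_keys(square_pixels(edit$center, edit$radius))
      in_f <- ref$markers[vapply(ref$markers,
                                 function(m) m$frame == edit$frame, TRUE)]
      for (m in in_f)
        if (any(px %in% pixel_keys(m$pixels)))
          stop("script error: spurious marker overlaps track ", m$label,
               " in frame ", edit$frame)
    },
    merge = {
      a <- track_row(ref, edit$label_a)
      b <- track_row(ref, edit$label_b)
      if (edit$label_a == edit$label_b)
        stop("script error: cannot merge a track with itself")
      if (a$t_init != b$t_init || a$t_end != b$t_end)
        stop("script error: merge requires identical track spans")
      if (!is.na(a$parent) || !is.na(b$parent) ||
          length(children_of(ref, a$label)) ||
          length(children_of(ref, b$label)))
        stop("script error: merge requires parentless, childless tracks")
    },
    cut_edge = {
      tr <- track_row(ref, edit$label)
      if (edit$frame < tr$t_init || edit$frame >= tr$t_end)
        stop("script error: track ", edit$label,
             " has no link between frames ", edit$frame, " and ",
             edit$frame + 1L)
    },
    add_false_edge = {
      pr <- track_row(ref, edit$parent)
      ch <- track_row(ref, edit$child)
      if (!is.na(ch$parent))
        stop("script error: track ", edit$child, " already has a parent")
      if (pr$t_end >= ch$t_init)
        stop("script error: false parent must terminate before the child ",
             "starts")
    },
    flip_semantics = {
      mo <- track_row(ref, edit$mother)
      kids <- ref$tracks[!is.na(ref$tracks$parent) &
                           ref$tracks$parent == edit$mother, ]
      if (!nrow(kids))
        stop("script error: track ", edit$mother, " has no children")
      if (!any(kids$t_init == mo$t_end + 1L))
        stop("script error: no child of track ", edit$mother,
             " starts right after it ends")
    })
  invisible(TRUE)
}

# Per-edit predicted count deltas (see ?edit_script_edits).
edit_delta <- function(edit, ref, ref_graph) {
  z <- c(NS = 0L, FN = 0L, FP = 0L, ED = 0L, EA = 0L, EC = 0L)
  switch(edit$type,
    delete_vertex = {
      z["FN"] <- 1L
      z["EA"] <- ref_degree(ref_graph, marker_key(edit$label, edit$frame))
    },
    add_spurious = z["FP"] <- 1L,
    merge = {
      a <- track_row(ref, edit$label_a)
      f <- a$t_end - a$t_init + 1L
      z["NS"] <- f
      z["EA"] <- 2L * (f - 1L)
    },
    cut_edge = z["EA"] <- 1L,
    add_false_edge = z["ED"] <- 1L,
    flip_semantics = {
      kids <- children_of(ref, edit$mother)
      z["EC"] <- 1L
      z["EA"] <- length(kids) - 1L
    })
  z
}

#' Corrupt a reference result with a script of known errors
#'
#' Applies the edits of `script` to a copy of `ref` and returns both the
#' corrupted (but structurally valid) computed result and the expected error
#' counts, obtained by summing the per-edit deltas documented in
#' [edit_script_edits].  The deltas only add when the edit sites are pairwise
#' disjoint (no shared markers or incident edges), which is enforced.
#'
#' @param ref A valid reference [tracking_result()].
#' @param script An [edit_script()].
#' @return List with elements `result` (the computed [tracking_result()]) and
#'   `expected` (an [error_counts()] object).
#' @examples
#' ref <- generate_reference(lineage_params(n_frames = 5, n_initial = 3,
#'                                          p_divide = 0, p_disappear = 0,
#'                                          p_appear = 0))
#' out <- inject_errors(ref, edit_script(edit_delete_vertex(1, 2)))
#' out$expected  # FN = 1, EA = 2
#' @export
inject_errors <- function(ref, script) {
  stopifnot(inherits(ref, "tracking_result"), inherits(script, "edit_script"))
  bad <- validate_tracking_result(ref)
  if (length(bad)) stop("invalid reference: ", bad[1L])
  ref_graph <- tracks_to_graph(ref)
  sites <- lapply(script$edits, edit_site, ref = ref, ref_graph = ref_graph)
  flat <- unlist(sites)
  if (anyDuplicated(flat))
    stop("script error: edit sites overlap at marker ",
         flat[duplicated(flat)][1L])
  spurious <- Filter(function(e) e$type == "add_spurious", script$edits)
  if (length(spurious) > 1L) {
    for (i in seq_along(spurious)[-1L]) for (j in seq_len(i - 1L)) {
      a <- spurious[[i]]; b <- spurious[[j]]
      if (a$frame == b$frame &&
          any(pixel_keys(square_pixels(a$center, a$radius)) %in%
              pixel_keys(square_pixels(b$center, b$radius))))
        stop("script error: spurious markers overlap in frame ", a$frame)
    }
  }
  for (e in script$edits) check_edit(e, ref, ref_graph)

  # working representation: nodes + semantic edges, rebuilt into tracks later
  nodes <- ref$markers
  edges <- ref_graph$edges
  drop_edges_at <- function(edges, key)
    edges[edges$from != key & edges$to != key, , drop = FALSE]
  spur_label <- max(c(0L, ref$tracks$label))
  expected <- c(NS = 0L, FN = 0L, FP = 0L, ED = 0L, EA = 0L, EC = 0L)

  for (e in script$edits) {
    expected <- expected + edit_delta(e, ref, ref_graph)
    switch(e$type,
      delete_vertex = {
        key <- marker_key(e$label, e$frame)
        nodes[[key]] <- NULL
        edges <- drop_edges_at(edges, key)
      },
      add_spurious = {
        spur_label <- spur_label + 1L
        m <- marker(spur_label, e$frame, square_pixels(e$center, e$radius))
        nodes[[marker_key(spur_label, e$frame)]] <- m
      },
      merge = {
        a <- track_row(ref, e$label_a)
        for (f in a$t_init:a$t_end) {
          ka <- marker_key(e$label_a, f)
          kb <- marker_key(e$label_b, f)
          nodes[[ka]] <- marker(e$label_a, f,
                                rbind(nodes[[ka]]$pixels,
                                      nodes[[kb]]$pixels))
          nodes[[kb]] <- NULL
          edges$from[edges$from == kb] <- ka
          edges$to[edges$to == kb] <- ka
        }
        edges <- unique(edges)
      },
      cut_edge = {
        kf <- marker_key(e$label, e$frame)
        kt <- marker_key(e$label, e$frame + 1L)
        edges <- edges[!(edges$from == kf & edges$to == kt), , drop = FALSE]
      },
      add_false_edge = {
        pr <- track_row(ref, e$parent)
        ch <- track_row(ref, e$child)
        edges <- rbind(edges,
                       data.frame(from = marker_key(pr$label, pr$t_end),
                                  to = marker_key(ch$label, ch$t_init),
                                  semantics = "P"))
      },
      flip_semantics = {
        mo <- track_row(ref, e$mother)
        kids <- ref$tracks[!is.na(ref$tracks$parent) &
                             ref$tracks$parent == e$mother, ]
        cont <- min(kids$label[kids$t_init == mo$t_end + 1L])
        mk <- marker_key(mo$label, mo$t_end)
        for (kid in kids$label) {
          kk <- marker_key(kid, kids$t_init[kids$label == kid])
          sel <- edges$from == mk & edges$to == kk
          if (kid == cont) edges$semantics[sel] <- "T"
          else edges <- edges[!sel, , drop = FALSE]
        }
      })
  }
  comp <- materialize_result(nodes, edges, ref$n_frames)
  list(result = comp,
       expected = error_counts(NS = expected[["NS"]], FN = expected[["FN"]],
                               FP = expected[["FP"]], ED = expected[["ED"]],
                               EA = expected[["EA"]], EC = expected[["EC"]],
                               n_ref_vertices = length(ref$markers),
                               n_ref_edges = nrow(ref_graph$edges)))
}

# Rebuild a tracking_result from loose nodes and semantic edges: chains of
# track links become tracks (freshly labelled in deterministic order), parent
# links become parent fields.
materialize_result <- function(nodes, edges, n_frames) {
  keys <- names(nodes)
  tlinks <- edges[edges$semantics == "T", , drop = FALSE]
  plinks <- edges[edges$semantics == "P", , drop = FALSE]
  succ <- stats::setNames(tlinks$to, tlinks$from)
  has_pred <- keys %in% tlinks$to
  heads <- keys[!has_pred]
  chains <- lapply(heads, function(h) {
    chain <- h
    while (!is.na(nxt <- succ[utils::tail(chain, 1L)][[1L]])) {
      chain <- c(chain, nxt)
      if (length(chain) > length(keys)) stop("cycle in track links")
    }
    chain
  })
  # deterministic labelling: by start frame, then first marker's coordinates
  if (length(chains)) {
    d <- ncol(nodes[[chains[[1L]][1L]]]$pixels)
    head_frame <- vapply(chains, function(ch) nodes[[ch[1L]]]$frame, 0L)
    head_pos <- t(vapply(chains, function(ch)
      as.numeric(nodes[[ch[1L]]]$pixels[1L, ]), numeric(d)))
    ord <- do.call(order, c(list(head_frame),
                            lapply(seq_len(d),
                                   function(j) head_pos[, j])))
    chains <- chains[ord]
  }
  chain_of <- integer(0)
  for (i in seq_along(chains))
    chain_of[chains[[i]]] <- i
  tr <- data.frame(
    label = seq_along(chains),
    t_init = vapply(chains, function(ch) nodes[[ch[1L]]]$frame, 0L),
    t_end = vapply(chains, function(ch)
      nodes[[ch[length(ch)]]]$frame, 0L),
    parent = NA_integer_)
  for (i in seq_len(nrow(plinks))) {
    child_chain <- chain_of[[plinks$to[i]]]
    parent_chain <- chain_of[[plinks$from[i]]]
    if (chains[[child_chain]][1L] != plinks$to[i])
      stop("parent link does not target a track start")
    if (utils::tail(chains[[parent_chain]], 1L) != plinks$from[i])
      stop("parent link does not leave a track end")
    tr$parent[child_chain] <- parent_chain
  }
  markers <- list()
  for (i in seq_along(chains)) for (key in chains[[i]]) {
    n <- nodes[[key]]
    markers[[length(markers) + 1L]] <- marker(i, n$frame, n$pixels)
  }
  tracking_result(n_frames, tr, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a random, site-disjoint edit script
#'
#' Samples up to `n_edits` applicable edits of the requested types from a
#' reference result, greedily keeping only edits whose sites do not touch
#' already-used markers.  The returned script may be shorter than requested
#' when the reference offers too few disjoint sites.
#'
#' @param ref A valid reference [tracking_result()].
#' @param n_edits Number of edits to attempt.
#' @param types Edit types to draw from.
#' @param seed Integer seed.
#' @return An [edit_script()].
#' @export
random_edit_script <- function(ref, n_edits = 4L,
                               types = c("delete_vertex", "add_spurious",
                                         "merge", "cut_edge",
                                         "add_false_edge", "flip_semantics"),
                               seed = 1L) {
  stopifnot(inherits(ref, "tracking_result"))
  ref_graph <- tracks_to_graph(ref)
  with_seed(seed, {
    used <- character()
    spurious_px <- list()  # frame -> pixel keys already claimed
    edits <- list()
    occupied <- function(frame) {
      in_f <- ref$markers[vapply(ref$markers,
                                 function(m) m$frame == frame, TRUE)]
      c(unlist(lapply(in_f, function(m) pixel_keys(m$pixels))),
        spurious_px[[as.character(frame)]])
    }
    d <- ncol(ref$markers[[1L]]$pixels %||% matrix(0L, 1L, 2L))
    shape_hi <- if (length(ref$markers))
      Reduce(pmax, lapply(ref$markers, function(m)
        apply(m$pixels, 2L, max))) else rep(10L, d)
    propose <- function(type) {
      tr <- ref$tracks
      switch(type,
        delete_vertex = {
          if (!nrow(tr)) return(NULL)
          i <- sample(nrow(tr), 1L)
          f <- sample(tr$t_init[i]:tr$t_end[i], 1L)
          edit_delete_vertex(tr$label[i], f)
        },
        add_spurious = {
          f <- sample(ref$n_frames, 1L) - 1L
          occ <- occupied(f)
          for (a in seq_len(25L)) {
            ctr <- vapply(seq_len(d), function(j)
              sample(2:max(2L, shape_hi[j] + 4L), 1L), 0L)
            px <- pixel_keys(square_pixels(ctr, 1L))
            if (!any(px %in% occ)) return(edit_add_spurious(f, ctr, 1L))
          }
          NULL
        },
        merge = {
          free <- tr[is.na(tr$parent) &
                       !(tr$label %in% tr$parent[!is.na(tr$parent)]), ]
          if (nrow(free) < 2L) return(NULL)
          spans <- split(free$label, paste(free$t_init, free$t_end))
          spans <- spans[lengths(spans) >= 2L]
          if (!length(spans)) return(NULL)
          pick <- sample(unlist(sample(spans, 1L)), 2L)
          edit_merge(pick[1L], pick[2L])
        },
        cut_edge = {
          long <- tr[tr$t_end > tr$t_init, ]
          if (!nrow(long)) return(NULL)
          i <- sample(nrow(long), 1L)
          f <- sample(long$t_init[i]:(long$t_end[i] - 1L), 1L)
          edit_cut_edge(long$label[i], f)
        },
        add_false_edge = {
          orphan <- tr[is.na(tr$parent), ]
          if (!nrow(orphan)) return(NULL)
          for (a in seq_len(10L)) {
            i <- sample(nrow(orphan), 1L)
            par <- tr[tr$t_end < orphan$t_init[i] &
                        tr$label != orphan$label[i], ]
            if (nrow(par))
              return(edit_add_false_edge(orphan$label[i],
                                         par$label[sample(nrow(par), 1L)]))
          }
          NULL
        },
        flip_semantics = {
          mothers <- unique(tr$parent[!is.na(tr$parent)])
          ok <- vapply(mothers, function(mo) {
            kids <- tr[!is.na(tr$parent) & tr$parent == mo, ]
            any(kids$t_init == tr$t_end[tr$label == mo] + 1L)
          }, TRUE)
          if (!any(ok)) return(NULL)
          edit_flip_semantics(sample(rep(mothers[ok], 2L), 1L))
        })
    }
    for (i in seq_len(n_edits)) {
      type <- sample(rep(types, 2L), 1L)
      e <- propose(type)
      if (is.null(e)) next
      ok <- !inherits(tryCatch(check_edit(e, ref, ref_graph),
                               error = function(err) err), "error")
      if (!ok) next
      site <- edit_site(e, ref, ref_graph)
      if (any(site %in% used)) next
      if (e$type == "add_spurious") {
        fkey <- as.character(e$frame)
        px <- pixel_keys(square_pixels(e$center, e$radius))
        if (any(px %in% spurious_px[[fkey]])) next
        spurious_px[[fkey]] <- c(spurious_px[[fkey]], px)
      }
      used <- c(used, site)
      edits[[length(edits) + 1L]] <- e
    }
    edit_script(edits)
  })
}
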