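## Synthetic two-channel neuron images: filled nuclear discs plus soma discs
## with branching neurite trees drawn as straight ~3-px strokes on the
## integer lattice.  The generative tree (roots, nodes, extremities,
## segments, per-segment Euclidean lengths) is stored alongside the image as
## exact ground truth for the morphometry pipeline.

#' Parameters of the synthetic neuron-image generator
#'
#' Somas are placed with a minimum separation, each marker-positive soma
#' grows a number of neurites drawn uniformly from `neurites_per_soma`;
#' every neurite is a binary tree: a straight segment (length uniform in
#' `segment_length`) that, at its distal end, either bifurcates (probability
#' `branch_probability`, up to `max_branch_depth` levels) or terminates.
#' Bifurcations always produce two viable daughter branches — if the two
#' daughters cannot both be drawn without colliding with existing
#' structures, the branch point is abandoned and the tip becomes an
#' extremity — so the stored tree is exactly the rendered one: every node
#' has degree 3, every root degree 1, and `segments = nodes + extremities`
#' per tree.
#'
#' @param n_somas Number of somas.
#' @param soma_radius Soma disc radius, px.
#' @param neurites_per_soma Length-2 integer range (inclusive) of neurites
#'   per marker-positive soma; equal values give a fixed count.
#' @param branch_probability Bifurcation probability per segment end.
#' @param max_branch_depth Maximum number of bifurcation levels.
#' @param segment_length Length-2 numeric range of segment lengths, px.
#' @param image_size Length-2 integer image size, px.
#' @param marker_positive_fraction Fraction of somas rendered in the
#'   neurite-marker channel (negatives get a nucleus only and no neurites).
#' @param noise_sd Gaussian intensity noise SD added to both channels.
#' @param seed Integer seed used by [generate_neuron_image()] unless
#'   overridden there.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(n_somas = 5, soma_radius = 8,
                            neurites_per_soma = c(2, 4),
                            branch_probability = 0.35,
                            max_branch_depth = 3,
                            segment_length = c(25, 60),
                            image_size = c(256, 256),
                            marker_positive_fraction = 1,
                            noise_sd = 0.02, seed = 1L) {
  n_somas <- check_count(n_somas, "n_somas", lower = 0L)
  check_number(soma_radius, "soma_radius", lower = 2)
  check_number(branch_probability, "branch_probability", lower = 0, upper = 1)
  max_branch_depth <- check_count(max_branch_depth, "max_branch_depth",
                                  lower = 0L)
  check_number(marker_positive_fraction, "marker_positive_fraction",
               lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  stop_if(length(neurites_per_soma) != 2 ||
            neurites_per_soma[1] > neurites_per_soma[2] ||
            neurites_per_soma[1] < 0,
          "`neurites_per_soma` must be an increasing length-2 range")
  stop_if(length(segment_length) != 2 ||
            segment_length[1] > segment_length[2] || segment_length[1] < 12,
          "`segment_length` must be an increasing length-2 range, min 12 px")
  stop_if(length(image_size) != 2 || any(image_size < 8 * soma_radius),
          "`image_size` must be a length-2 vector comfortably larger than ",
          "the somas")
  structure(list(n_somas = n_somas, soma_radius = soma_radius,
                 neurites_per_soma = as.integer(neurites_per_soma),
                 branch_probability = branch_probability,
                 max_branch_depth = max_branch_depth,
                 segment_length = segment_length,
                 image_size = as.integer(image_size),
                 marker_positive_fraction = marker_positive_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "morphology_spec")
}

disc_pixels <- function(cx, cy, r, w, h) {
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
  cbind(g$x, g$y)
}

## Rasterize a straight stroke of ~3 px width (cross-shaped footprint along
## the path, which skeletonizes stably) from p0 toward angle theta over
## length len; returns integer pixel matrix (x, y), deduplicated.
stroke_pixels <- function(p0, theta, len, w, h) {
  tt <- seq(0, len, by = 0.4)
  xs <- p0[1] + tt * cos(theta)
  ys <- p0[2] + tt * sin(theta)
  px <- cbind(round(xs), round(ys))
  px <- rbind(px, cbind(px[, 1] + 1L, px[, 2]),
              cbind(px[, 1] - 1L, px[, 2]),
              cbind(px[, 1], px[, 2] + 1L),
              cbind(px[, 1], px[, 2] - 1L))
  px <- px[px[, 1] >= 1 & px[, 1] <= w & px[, 2] >= 1 & px[, 2] <= h, ,
           drop = FALSE]
  unique(px)
}

pix_index <- function(px, w) (px[, 2] - 1L) * w + px[, 1]

#' Generate a synthetic two-channel neuron image with ground truth
#'
#' @param spec A [morphology_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of class `neuron_image_sim` with elements
#'   \describe{
#'     \item{image}{class `neuron_image`: matrices `nuclei` and `marker`
#'       (intensities in \[0, 1\]) plus `pixel_size` (NA, lengths are in
#'       px);}
#'     \item{truth}{class `morphology_ground_truth`: `somas` (centre,
#'       radius, marker positivity), `vertices` (`soma`, `id`, `x`, `y`,
#'       `type` in root/node/extremity, `path_length` from the root),
#'       `segments` (`soma`, `from`, `to`, `length`, `depth`), and
#'       `phenotypes` — the six per-soma neurite phenotypes implied by the
#'       generative tree.}
#'   }
#' @export
generate_neuron_image <- function(spec, seed = spec$seed) {
  stop_if(!inherits(spec, "morphology_spec"),
          "`spec` must be a morphology_spec")
  w <- spec$image_size[1]; h <- spec$image_size[2]
  r <- spec$soma_radius
  with_seed(seed, {
    ## --- soma placement: rejection sampling with a separation margin ----
    margin <- r + 12
    min_sep <- 2 * r + 24
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < spec$n_somas) {
      tries <- tries + 1L
      stop_if(tries > 5000L,
              "image too small to place %d non-overlapping somas",
              spec$n_somas)
      cand <- c(stats::runif(1, margin, w - margin),
                stats::runif(1, margin, h - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >=
                min_sep)) {
        centers <- rbind(centers, cand)
      }
    }
    n_pos <- round(spec$marker_positive_fraction * spec$n_somas)
    positive <- rep(FALSE, spec$n_somas)
    if (n_pos > 0) positive[sample(spec$n_somas, n_pos)] <- TRUE

    ## Two collision maps: strokes already drawn, and a soma keep-out zone
    ## (radius r + 10) that keeps every stroke far enough from foreign somas
    ## that no stroke end can be mistaken for a root of one.
    stroke_occ <- matrix(FALSE, w, h)
    soma_ko <- matrix(FALSE, w, h)
    for (s in seq_len(spec$n_somas)) {
      soma_ko[pix_index(disc_pixels(centers[s, 1], centers[s, 2], r + 10,
                                    w, h), w)] <- TRUE
    }

    vertices <- list(); segments <- list(); stroke_list <- list()
    vid <- 0L
    new_vertex <- function(soma, x, y, type, path_length) {
      vid <<- vid + 1L
      vertices[[vid]] <<- data.frame(soma = soma, id = vid, x = x, y = y,
                                     type = type, path_length = path_length)
      vid
    }
    border_margin <- 3

    ## Propose one straight segment; truncates at the image border; rejects
    ## on collision.  The test runs on the 1-px dilation of the stroke, so
    ## accepted strokes keep a clear gap from every existing structure and
    ## never merge with one under 8-connectivity; the only contacts
    ## tolerated are the explicitly allowed pixels (the parent stroke and
    ## the sibling branch near a shared branch point) and, for first
    ## segments, the own soma's keep-out zone near the start.  Returns NULL
    ## on failure.
    try_segment <- function(p0, theta, allowed_idx = integer(0),
                            forbidden_idx = integer(0), from_soma = FALSE) {
      len <- stats::runif(1, spec$segment_length[1], spec$segment_length[2])
      ux <- cos(theta); uy <- sin(theta)
      tmax <- len
      if (ux > 0) tmax <- min(tmax, (w - border_margin - p0[1]) / ux)
      if (ux < 0) tmax <- min(tmax, (1 + border_margin - p0[1]) / ux)
      if (uy > 0) tmax <- min(tmax, (h - border_margin - p0[2]) / uy)
      if (uy < 0) tmax <- min(tmax, (1 + border_margin - p0[2]) / uy)
      if (tmax < 12) return(NULL)
      len <- tmax
      px <- stroke_pixels(p0, theta, len, w, h)
      dil <- do.call(rbind, lapply(list(c(0, 0), c(1, 0), c(-1, 0),
                                        c(0, 1), c(0, -1), c(1, 1),
                                        c(1, -1), c(-1, 1), c(-1, -1)),
                                   function(d) {
                                     cbind(px[, 1] + d[1], px[, 2] + d[2])
                                   }))
      dil <- unique(dil[dil[, 1] >= 1 & dil[, 1] <= w &
                          dil[, 2] >= 1 & dil[, 2] <= h, , drop = FALSE])
      idx <- pix_index(dil, w)
      viol <- (stroke_occ[idx] | idx %in% forbidden_idx) &
        !(idx %in% allowed_idx)
      if (any(viol)) return(NULL)
      d2 <- (dil[, 1] - p0[1])^2 + (dil[, 2] - p0[2])^2
      soma_clear <- if (from_soma) 169 else 0                     # 13 px
      idx_soma <- pix_index(dil[d2 > soma_clear, , drop = FALSE], w)
      if (any(soma_ko[idx_soma])) return(NULL)
      list(pixels = px, end = c(p0[1] + len * ux, p0[2] + len * uy),
           length = len, theta = theta)
    }

    commit_segment <- function(seg, soma, from_id, depth, cum) {
      stroke_occ[pix_index(seg$pixels, w)] <<- TRUE
      stroke_list[[length(stroke_list) + 1L]] <<- seg$pixels
      seg_end_cum <- cum + seg$length
      seg_id <- length(segments) + 1L
      segments[[seg_id]] <<- data.frame(soma = soma, from = from_id,
                                        to = NA_integer_,
                                        length = seg$length, depth = depth)
      list(seg_id = seg_id, cum = seg_end_cum)
    }

    ## Growth from a committed segment's distal end: bifurcate (both
    ## daughters must fit) or terminate as an extremity.
    grow_from <- function(soma, seg, seg_id, depth, cum) {
      branch <- depth <= spec$max_branch_depth &&
        stats::runif(1) < spec$branch_probability
      if (branch) {
        parent_idx <- pix_index(seg$pixels, w)
        for (attempt in 1:4) {
          d1 <- stats::runif(1, pi / 6, 5 * pi / 18)   # 30-50 degrees
          d2 <- stats::runif(1, pi / 6, 5 * pi / 18)
          segA <- try_segment(seg$end, seg$theta + d1,
                              allowed_idx = parent_idx)
          if (is.null(segA)) next
          dA <- (segA$pixels[, 1] - seg$end[1])^2 +
            (segA$pixels[, 2] - seg$end[2])^2
          segB <- try_segment(seg$end, seg$theta - d2,
                              allowed_idx = c(parent_idx,
                                              pix_index(segA$pixels[dA <= 36,
                                                        , drop = FALSE], w)),
                              forbidden_idx = pix_index(
                                segA$pixels[dA > 36, , drop = FALSE], w))
          if (is.null(segB)) next
          node_id <- new_vertex(soma, seg$end[1], seg$end[2], "node", cum)
          segments[[seg_id]]$to <<- node_id
          for (child in list(segA, segB)) {
            cc <- commit_segment(child, soma, node_id, depth + 1L, cum)
            grow_from(soma, child, cc$seg_id, depth + 1L, cc$cum)
          }
          return(invisible(NULL))
        }
      }
      ext_id <- new_vertex(soma, seg$end[1], seg$end[2], "extremity", cum)
      segments[[seg_id]]$to <<- ext_id
      invisible(NULL)
    }

    for (s in seq_len(spec$n_somas)) {
      if (!positive[s]) next
      m_choices <- spec$neurites_per_soma[1]:spec$neurites_per_soma[2]
      m <- m_choices[sample.int(length(m_choices), 1)]
      if (m == 0) next
      base <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(m) - 1) / m
      for (a in base) {
        grown <- FALSE
        for (attempt in 1:3) {
          theta <- a + stats::runif(1, -pi / 18, pi / 18)
          p0 <- centers[s, ] + r * c(cos(theta), sin(theta))
          seg <- try_segment(p0, theta, from_soma = TRUE)
          if (is.null(seg)) next
          root_id <- new_vertex(s, p0[1], p0[2], "root", 0)
          cc <- commit_segment(seg, s, root_id, 1L, 0)
          grow_from(s, seg, cc$seg_id, 1L, cc$cum)
          grown <- TRUE
          break
        }
        if (!grown) next   # crowded sector: this neurite is not created
      }
    }

    vertices <- if (length(vertices)) do.call(rbind, vertices) else
      data.frame(soma = integer(), id = integer(), x = numeric(),
                 y = numeric(), type = character(), path_length = numeric())
    segments <- if (length(segments)) do.call(rbind, segments) else
      data.frame(soma = integer(), from = integer(), to = integer(),
                 length = numeric(), depth = integer())
    rownames(vertices) <- rownames(segments) <- NULL

    ## --- render ---------------------------------------------------------
    nuclei <- matrix(0, w, h); marker <- matrix(0, w, h)
    nuc_r <- max(3, round(0.6 * r))
    for (s in seq_len(spec$n_somas)) {
      nuclei[pix_index(disc_pixels(centers[s, 1], centers[s, 2], nuc_r,
                                   w, h), w)] <- 0.9
      if (positive[s]) {
        marker[pix_index(disc_pixels(centers[s, 1], centers[s, 2], r, w, h),
                         w)] <- 0.8
      }
    }
    for (px in stroke_list) marker[pix_index(px, w)] <- 0.7
    if (spec$noise_sd > 0) {
      nuclei <- nuclei + matrix(stats::rnorm(w * h, 0, spec$noise_sd), w, h)
      marker <- marker + matrix(stats::rnorm(w * h, 0, spec$noise_sd), w, h)
    }
    nuclei <- pmin(pmax(nuclei, 0), 1)
    marker <- pmin(pmax(marker, 0), 1)

    somas <- data.frame(soma = seq_len(spec$n_somas),
                        x = centers[, 1], y = centers[, 2],
                        radius = r, marker_positive = positive)
    truth <- structure(list(somas = somas, vertices = vertices,
                            segments = segments,
                            phenotypes = truth_phenotypes(somas, vertices,
                                                          segments)),
                       class = "morphology_ground_truth")
    structure(list(image = structure(list(nuclei = nuclei, marker = marker,
                                          pixel_size = NA_real_),
                                     class = "neuron_image"),
                   truth = truth,
                   provenance = list(spec = unclass(spec), seed = seed)),
              class = "neuron_image_sim")
  })
}

## Per-soma phenotype summary implied by the generative tree: counts come
## from vertex types, total length from the segment table, and the maximum
## neurite length from the root path length accumulated at each extremity.
truth_phenotypes <- function(somas, vertices, segments) {
  out <- data.frame(soma = somas$soma, max_neurite_length = 0,
                    total_neurite_length = 0, n_extremities = 0L,
                    n_roots = 0L, n_segments = 0L, n_nodes = 0L)
  for (i in seq_len(nrow(out))) {
    s <- out$soma[i]
    v <- vertices[vertices$soma == s, , drop = FALSE]
    sg <- segments[segments$soma == s, , drop = FALSE]
    out$n_roots[i] <- sum(v$type == "root")
    out$n_nodes[i] <- sum(v$type == "node")
    out$n_extremities[i] <- sum(v$type == "extremity")
    out$n_segments[i] <- nrow(sg)
    out$total_neurite_length[i] <- sum(sg$length)
    ext <- v[v$type == "extremity", , drop = FALSE]
    if (nrow(ext) > 0) {
      out$max_neurite_length[i] <- max(ext$path_length)
    }
  }
  out
}
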