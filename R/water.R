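#' A single frame of water coordinates
#'
#' Container for one time frame of rigid three-site waters: oxygen
#' positions and the two hydrogens of each molecule, optionally in an
#' orthorhombic periodic box.
#'
#' @param oxygen N x 3 matrix of oxygen coordinates, Angstrom.
#' @param hydrogen N x 2 x 3 array of hydrogen coordinates, Angstrom
#'   (two hydrogens per oxygen, same molecule order).
#' @param box optional length-3 orthorhombic box lengths, Angstrom; when
#'   supplied, distance computations use the minimum-image convention.
#' @param frame_index integer frame label.
#' @return An object of class `water_frame`.
#' @export
water_frame <- function(oxygen, hydrogen, box = NULL, frame_index = 1L) {
  oxygen <- .as_points(oxygen)
  n <- nrow(oxygen)
  if (n == 0) {
    hydrogen <- array(numeric(0), dim = c(0, 2, 3))
  } else {
    if (length(dim(hydrogen)) != 3 || any(dim(hydrogen) != c(n, 2, 3)))
      .stop_domain("'hydrogen' must be an N x 2 x 3 array matching 'oxygen'")
    for (h in 1:2) {
      hmat <- matrix(hydrogen[, h, ], ncol = 3)
      d <- sqrt(rowSums((hmat - oxygen)^2))
      if (any(d <= 0.5 | d >= 1.5))
        .stop_domain("malformed hydrogens: O-H distances must lie in ",
                     "(0.5, 1.5) Angstrom")
    }
  }
  if (!is.null(box)) {
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      .stop_domain("'box' must be 3 positive lengths")
  }
  structure(list(oxygen = oxygen, hydrogen = hydrogen, box = box,
                 frame_index = as.integer(frame_index)),
            class = "water_frame")
}

#' @export
print.water_frame <- function(x, ...) {
  cat(sprintf("water_frame %d: %d molecules%s\n", x$frame_index,
              nrow(x$oxygen),
              if (is.null(x$box)) "" else
                sprintf(", box %s A", paste(signif(x$box, 4), collapse = " x "))))
  invisible(x)
}

.n_waters <- function(frame) nrow(frame$oxygen)

## minimum-image displacement of a matrix of deltas
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## all unordered pairs (i < j) with |O_i - O_j| < cutoff, block-vectorised
.neighbor_pairs <- function(pos, cutoff, box = NULL, block = 256L) {
  n <- nrow(pos)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0),
                               r = numeric(0)))
  out_i <- list(); out_j <- list(); out_r <- list(); nb <- 0L
  for (start in seq(1L, n - 1L, by = block)) {
    rows <- start:min(start + block - 1L, n - 1L)
    for (k in seq_along(rows)) {
      i <- rows[k]
      js <- (i + 1L):n
      d <- pos[js, , drop = FALSE] -
        matrix(pos[i, ], nrow = length(js), ncol = 3, byrow = TRUE)
      d <- .min_image(d, box)
      r2 <- rowSums(d * d)
      hit <- which(r2 < cutoff^2)
      if (length(hit)) {
        nb <- nb + 1L
        out_i[[nb]] <- rep.int(i, length(hit))
        out_j[[nb]] <- js[hit]
        out_r[[nb]] <- sqrt(r2[hit])
      }
    }
  }
  data.frame(i = unlist(out_i), j = unlist(out_j), r = unlist(out_r))
}

#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond is counted between two waters when their oxygen-oxygen
#' distance is below `r_OO_max` and the angle at the donor oxygen between
#' the donated O-H bond and the O-O vector is below `angle_OOH_max`.
#'
#' @param r_OO_max oxygen-oxygen distance cutoff, Angstrom. Default 3.5.
#' @param angle_OOH_max donor O-O-H angle cutoff, degrees. Default 30.
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(r_OO_max = 3.5, angle_OOH_max = 30) {
  if (!is.finite(r_OO_max) || r_OO_max <= 0)
    .stop_domain("'r_OO_max' must be > 0")
  if (!is.finite(angle_OOH_max) || angle_OOH_max <= 0 || angle_OOH_max >= 180)
    .stop_domain("'angle_OOH_max' must lie in (0, 180)")
  structure(list(r_OO_max = r_OO_max, angle_OOH_max = angle_OOH_max),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in a water frame
#'
#' Applies the geometric criterion of [hbond_criterion()] to every water
#' pair: a directed donor-to-acceptor edge is recorded when the O-O
#' distance is below the cutoff and the angle at the donor oxygen between
#' the O-O vector and the donating O-H bond is below the angle cutoff.
#' Each (donor, hydrogen) pair donates to at most one acceptor; when the
#' criterion admits several acceptors the nearest is kept. Minimum-image
#' distances are used when the frame has a box.
#'
#' @param frame a [water_frame()].
#' @param criterion an [hbond_criterion()].
#' @return An object of class `hbond_graph`: list with `edges` (data frame
#'   with columns `donor`, `hydrogen`, `acceptor`, `r_OO`), per-molecule
#'   `donor_count` and `acceptor_count`, and `n_molecules`.
#' @export
detect_hbonds <- function(frame, criterion = hbond_criterion()) {
  if (!inherits(frame, "water_frame"))
    .stop_domain("'frame' must be a water_frame")
  if (!inherits(criterion, "hbond_criterion"))
    .stop_domain("'criterion' must be an hbond_criterion")
  n <- .n_waters(frame)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), r_OO = numeric(0))
  if (n < 2) return(.new_hbond_graph(empty, n))
  pairs <- .neighbor_pairs(frame$oxygen, criterion$r_OO_max, frame$box)
  if (nrow(pairs) == 0) return(.new_hbond_graph(empty, n))
  cos_max <- cos(criterion$angle_OOH_max * pi / 180)
  ## ordered directions: (i -> j) and (j -> i)
  don <- c(pairs$i, pairs$j)
  acc <- c(pairs$j, pairs$i)
  r <- c(pairs$r, pairs$r)
  ov <- .min_image(frame$oxygen[acc, , drop = FALSE] -
                     frame$oxygen[don, , drop = FALSE], frame$box)
  keep <- list()
  for (h in 1:2) {
    hmat <- matrix(frame$hydrogen[, h, ], ncol = 3)
    hv <- .min_image(hmat[don, , drop = FALSE] -
                       frame$oxygen[don, , drop = FALSE], frame$box)
    cosang <- rowSums(ov * hv) / (r * sqrt(rowSums(hv * hv)))
    hit <- which(cosang > cos_max)
    if (length(hit))
      keep[[h]] <- data.frame(donor = don[hit], hydrogen = h,
                              acceptor = acc[hit], r_OO = r[hit])
  }
  edges <- do.call(rbind, keep)
  if (is.null(edges) || nrow(edges) == 0) return(.new_hbond_graph(empty, n))
  ## one acceptor per donated hydrogen: keep the closest
  edges <- edges[order(edges$donor, edges$hydrogen, edges$r_OO), ]
  dup <- duplicated(edges[, c("donor", "hydrogen")])
  edges <- edges[!dup, ]
  edges <- edges[order(edges$donor, edges$hydrogen, edges$acceptor), ]
  rownames(edges) <- NULL
  .new_hbond_graph(edges, n)
}

.new_hbond_graph <- function(edges, n) {
  structure(
    list(edges = edges,
         donor_count = tabulate(edges$donor, nbins = n),
         acceptor_count = tabulate(edges$acceptor, nbins = n),
         n_molecules = n),
    class = "hbond_graph"
  )
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("hbond_graph: %d molecules, %d hydrogen bonds (mean %.3f per molecule)\n",
              x$n_molecules, nrow(x$edges),
              if (x$n_molecules > 0) mean_hbonds_per_molecule(x) else 0))
  invisible(x)
}

#' Mean number of hydrogen bonds per molecule
#'
#' Mean over a molecule subset of the per-molecule degree, donated plus
#' accepted bonds.
#'
#' @param graph an [detect_hbonds()] result.
#' @param subset optional integer vector of molecule indices; default all.
#' @return dimensionless mean.
#' @export
mean_hbonds_per_molecule <- function(graph, subset = NULL) {
  if (!inherits(graph, "hbond_graph"))
    .stop_domain("'graph' must be an hbond_graph")
  if (graph$n_molecules == 0 && is.null(subset)) return(0)
  if (is.null(subset)) subset <- seq_len(graph$n_molecules)
  if (length(subset) == 0)
    .stop_domain("mean over an empty molecule subset is undefined")
  if (any(subset < 1 | subset > graph$n_molecules))
    .stop_domain("'subset' indices out of range")
  mean(graph$donor_count[subset] + graph$acceptor_count[subset])
}

#' Local hydrogen-bond network class of a water molecule
#'
#' Maps donor and acceptor counts to the local-network classes used in
#' water spectroscopy: DDAA (double donor-double acceptor, tetrahedral),
#' DDA, DAA, DA, and free (no bonds). Combinations outside those five
#' (for example two donors and no acceptor) are reported as `"other"`
#' rather than forced into a listed class.
#'
#' @param d,a donor and acceptor counts (vectorised, non-negative).
#' @return character vector of classes.
#' @examples
#' classify_local_network(2, 2) # "DDAA"
#' @export
classify_local_network <- function(d, a) {
  if (length(d) != length(a)) .stop_domain("'d' and 'a' lengths differ")
  if (any(d < 0) || any(a < 0) || any(d != round(d)) || any(a != round(a)))
    .stop_domain("'d' and 'a' must be non-negative integers")
  out <- rep("other", length(d))
  out[d >= 2 & a >= 2] <- "DDAA"
  out[d >= 2 & a == 1] <- "DDA"
  out[d == 1 & a >= 2] <- "DAA"
  out[d == 1 & a == 1] <- "DA"
  out[d == 0 & a == 0] <- "free"
  out
}

#' Network-class composition of a frame
#'
#' Convenience wrapper: per-molecule classes from an [detect_hbonds()]
#' graph, via [classify_local_network()].
#'
#' @param graph an `hbond_graph`.
#' @return character vector, one class per molecule.
#' @export
network_classes <- function(graph) {
  if (!inherits(graph, "hbond_graph"))
    .stop_domain("'graph' must be an hbond_graph")
  classify_local_network(graph$donor_count, graph$acceptor_count)
}

#' Partition waters into interfacial and bulk layers
#'
#' A molecule is interfacial when its oxygen lies within `layer_cutoff` of
#' the solute surface (signed distance in `[0, layer_cutoff]`, boundary
#' included); everything else is bulk, so the partition is total. Waters
#' found inside the solid (negative signed distance) are flagged with a
#' warning and counted as interfacial.
#'
#' @param frame a [water_frame()].
#' @param shape a [make_shape()] solute.
#' @param layer_cutoff layer thickness from the surface, Angstrom.
#'   Default 3.5, one water diameter.
#' @return An object of class `layer_labels`: list with `labels`
#'   (character, `"interfacial"`/`"bulk"`), `signed_distance`,
#'   `layer_cutoff`, `n`.
#' @export
classify_layers <- function(frame, shape, layer_cutoff = 3.5) {
  if (!inherits(frame, "water_frame"))
    .stop_domain("'frame' must be a water_frame")
  if (!is.finite(layer_cutoff) || layer_cutoff <= 0)
    .stop_domain("'layer_cutoff' must be > 0")
  n <- .n_waters(frame)
  if (n == 0) {
    return(structure(list(labels = character(0), signed_distance = numeric(0),
                          layer_cutoff = layer_cutoff, n = 0L),
                     class = "layer_labels"))
  }
  sd <- signed_distance(shape, frame$oxygen)
  if (any(sd < 0))
    warning(sum(sd < 0), " water(s) inside the solute (signed distance < 0);",
            " counted as interfacial")
  labels <- ifelse(sd <= layer_cutoff, "interfacial", "bulk")
  structure(list(labels = labels, signed_distance = sd,
                 layer_cutoff = layer_cutoff, n = as.integer(n)),
            class = "layer_labels")
}

#' @export
print.layer_labels <- function(x, ...) {
  cat(sprintf("layer_labels: %d interfacial, %d bulk (cutoff %.2f A)\n",
              sum(x$labels == "interfacial"), sum(x$labels == "bulk"),
              x$layer_cutoff))
  invisible(x)
}

#' Count interfacial-to-bulk transitions between two labelings
#'
#' Number of molecules labelled interfacial in `before` and bulk in
#' `after`; the reverse count and the net change are reported alongside.
#'
#' @param before,after [classify_layers()] results (or plain character
#'   vectors of `"interfacial"`/`"bulk"`) over the same molecules.
#' @return list with `n_interfacial_to_bulk`, `n_bulk_to_interfacial`,
#'   `net` (forward minus reverse).
#' @export
count_interfacial_to_bulk <- function(before, after) {
  lab <- function(x) if (inherits(x, "layer_labels")) x$labels else x
  b <- lab(before); a <- lab(after)
  if (length(b) != length(a))
    .stop_domain("'before' and 'after' must cover the same molecules")
  fwd <- sum(b == "interfacial" & a == "bulk")
  rev <- sum(b == "bulk" & a == "interfacial")
  list(n_interfacial_to_bulk = as.integer(fwd),
       n_bulk_to_interfacial = as.integer(rev),
       net = as.integer(fwd - rev))
}

#' Interfacial and bulk counts along a trajectory
#'
#' Per-frame layer counts against a fixed or frame-dependent solute
#' geometry; interfacial plus bulk always equals the number of waters.
#'
#' @param frames list of [water_frame()]s.
#' @param shape_at_frame either a single [make_shape()] object or a
#'   function of the frame position (1-based) returning one.
#' @param layer_cutoff layer thickness, Angstrom.
#' @return data frame with columns `frame`, `n_interfacial`, `n_bulk`.
#' @export
layer_counts_timeseries <- function(frames, shape_at_frame,
                                    layer_cutoff = 3.5) {
  if (length(frames) < 1) .stop_domain("need at least one frame")
  get_shape <- if (is.function(shape_at_frame)) shape_at_frame
               else function(i) shape_at_frame
  rows <- lapply(seq_along(frames), function(i) {
    ll <- classify_layers(frames[[i]], get_shape(i), layer_cutoff)
    data.frame(frame = frames[[i]]$frame_index,
               n_interfacial = sum(ll$labels == "interfacial"),
               n_bulk = sum(ll$labels == "bulk"))
  })
  do.call(rbind, rows)
}
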