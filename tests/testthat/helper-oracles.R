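## Independent oracles and small fixture builders shared across tests.

## All-pairs brute-force hydrogen-bond detection: plain double loop over
## ordered molecule pairs, trigonometry written out directly. Kept
## deliberately independent of the package's vectorised implementation.
brute_force_hbonds <- function(frame, criterion = hbond_criterion()) {
  n <- nrow(frame$oxygen)
  mi <- function(d, box) {
    if (!is.null(box)) for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
    d
  }
  res <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- mi(frame$oxygen[j, ] - frame$oxygen[i, ], frame$box)
    r <- sqrt(sum(v^2))
    if (r >= criterion$r_OO_max) next
    for (h in 1:2) {
      u <- mi(frame$hydrogen[i, h, ] - frame$oxygen[i, ], frame$box)
      ang <- acos(sum(u * v) / (r * sqrt(sum(u * u)))) * 180 / pi
      if (ang < criterion$angle_OOH_max)
        res <- rbind(res, data.frame(donor = i, hydrogen = h,
                                     acceptor = j, r_OO = r))
    }
  }
  if (is.null(res))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), r_OO = numeric(0)))
  ## nearest acceptor per donated hydrogen
  res <- res[order(res$donor, res$hydrogen, res$r_OO), ]
  res <- res[!duplicated(res[, c("donor", "hydrogen")]), ]
  res <- res[order(res$donor, res$hydrogen, res$acceptor), ]
  rownames(res) <- NULL
  res
}

## random frame of n waters in a cube of the given side
random_frame <- function(n, side = 12, box = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- matrix(stats::runif(3 * n, 0, side), n, 3)
  water_frame(o, random_hydrogens_for(o), box = box)
}

## hydrogens at 0.96 A, 104.5 deg internal angle, random orientation
## (re-derived here rather than calling the package internal)
random_hydrogens_for <- function(oxygen, d_OH = 0.96, angle = 104.5) {
  n <- nrow(oxygen)
  out <- array(NA_real_, c(n, 2, 3))
  for (i in seq_len(n)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3); v <- v - u * sum(u * v); v <- v / sqrt(sum(v^2))
    a <- angle * pi / 180
    w <- cos(a) * u + sin(a) * v
    out[i, 1, ] <- oxygen[i, ] + d_OH * u
    out[i, 2, ] <- oxygen[i, ] + d_OH * w
  }
  out
}

## two-water frame with prescribed O-O distance and donor O-H direction
## rotated by `angle_deg` away from the O-O axis
two_water_frame <- function(r_OO, angle_deg) {
  o <- rbind(c(0, 0, 0), c(r_OO, 0, 0))
  a <- angle_deg * pi / 180
  h <- array(NA_real_, c(2, 2, 3))
  h[1, 1, ] <- c(0.96 * cos(a), 0.96 * sin(a), 0)   # donor candidate
  h[1, 2, ] <- c(-0.3, 0, 0.9)                      # points away
  h[2, 1, ] <- c(r_OO + 0.3, 0, 0.9)
  h[2, 2, ] <- c(r_OO + 0.3, 0, -0.9)
  water_frame(o, h)
}
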