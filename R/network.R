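# regular grid of n x n cells spanning a square sheet, centered on the origin.
# `on_center = TRUE` shifts the grid by half a pitch so one cell sits exactly
# at the origin (used for the FS grid, so the stimulus center is sampled by
# an interneuron rather than falling between four of them).
grid_coords <- function(n, sheet, on_center = FALSE) {
  pitch <- sheet / n
  ax <- if (on_center) {
    (seq_len(n) - 1 - n / 2) * pitch      # includes 0 for even n
  } else {
    (seq_len(n) - 0.5) * pitch - sheet / 2
  }
  g <- expand.grid(x = ax, y = ax)  # x varies fastest: cell = iy*n + ix
  tibble(cell = seq_len(n * n), ix = rep(seq_len(n), n),
         iy = rep(seq_len(n), each = n), x = g$x, y = g$y)
}

# compress an edge list to CSR (0-based offsets/targets) over npre cells
edges_to_csr <- function(pre, post, npre) {
  o <- order(pre)
  pre <- pre[o]; post <- post[o]
  counts <- tabulate(pre, nbins = npre)
  list(offsets = as.integer(c(0, cumsum(counts))),
       targets = as.integer(post - 1L))
}

#' Build the two-dimensional cortical sheet
#'
#' Places `160*scale x 160*scale` pyramidal (P) cells and `32*scale x 32*scale`
#' fast-spiking (FS) cells on regular grids spanning a square sheet (1185 um a
#' side by default; both grids are centered so FS cells sit at the centers of
#' P-cell blocks) and samples the directed adjacency of the three
#' intracortical pathways. Each ordered pair is a single Bernoulli trial with
#' probability `peak * exp(-d^2 / (2 sigma^2))` of the pathway's profile;
#' self-connections are excluded.
#'
#' @param scale linear grid scaling in (0, 1]; 1 gives the full 160x160 /
#'   32x32 sheet. Smaller values keep the physical sheet size but coarsen the
#'   grids proportionally (useful for fast exploratory runs).
#' @param profiles named list of [connectivity_profile()]s (`pp`, `pfs`,
#'   `fsp`); defaults to [default_connectivity()].
#' @param sheet side of the square sheet (um).
#' @param seed optional integer seed for the wiring draw.
#' @return an object of class `cortical_net`.
#' @export
build_network <- function(scale = 1, profiles = default_connectivity(),
                          sheet = 1185, seed = NULL) {
  stopifnot(scale > 0, scale <= 1)
  n_p <- max(2L, as.integer(round(160 * scale)))
  n_fs <- max(2L, as.integer(round(32 * scale)))
  pc <- grid_coords(n_p, sheet)
  fc <- grid_coords(n_fs, sheet, on_center = TRUE)
  pitch_p <- sheet / n_p
  pitch_fs <- sheet / n_fs
  x0_p <- pc$x[1]; x0_fs <- fc$x[1]
  with_seed(seed, {
    pp <- sample_adjacency_cpp(pc$x, pc$y, x0_p, x0_p, pitch_p, n_p, n_p,
                               profiles$pp$peak, profiles$pp$sigma, 0L, 4)
    pfs <- sample_adjacency_cpp(pc$x, pc$y, x0_fs, x0_fs, pitch_fs, n_fs, n_fs,
                                profiles$pfs$peak, profiles$pfs$sigma, -1L, 4)
    fsp <- sample_adjacency_cpp(fc$x, fc$y, x0_p, x0_p, pitch_p, n_p, n_p,
                                profiles$fsp$peak, profiles$fsp$sigma, -1L, 4)
    structure(
      list(n_p_side = n_p, n_fs_side = n_fs, sheet = sheet, scale = scale,
           p_coords = pc, fs_coords = fc, profiles = profiles,
           edges = list(pp = pp, pfs = pfs, fsp = fsp),
           csr = list(pp = edges_to_csr(pp$pre, pp$post, n_p * n_p),
                      pfs = edges_to_csr(pfs$pre, pfs$post, n_p * n_p),
                      fsp = edges_to_csr(fsp$pre, fsp$post, n_fs * n_fs))),
      class = "cortical_net")
  })
}

#' @export
print.cortical_net <- function(x, ...) {
  cat("<cortical_net> ", x$n_p_side, "x", x$n_p_side, " P / ",
      x$n_fs_side, "x", x$n_fs_side, " FS cells on a ",
      x$sheet, " um sheet\n", sep = "")
  cat("edges: P->P ", length(x$edges$pp$pre), ", P->FS ",
      length(x$edges$pfs$pre), ", FS->P ", length(x$edges$fsp$pre), "\n",
      sep = "")
  invisible(x)
}

#' Network adjacency as a tidy edge list
#'
#' @param net a [build_network()] result.
#' @return tibble with columns `pathway`, `pre`, `post`.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "cortical_net"))
  purrr::map_dfr(names(net$edges), function(pw) {
    tibble(pathway = pw, pre = net$edges[[pw]]$pre, post = net$edges[[pw]]$post)
  })
}

#' Empirical connection frequency near zero distance
#'
#' Fraction of ordered pairs of a pathway closer than `d_max` that are
#' connected in a sampled realization; converges to the profile's peak as the
#' sample grows.
#'
#' @param net a [build_network()] result.
#' @param pathway `"pp"`, `"pfs"` or `"fsp"`.
#' @param d_max distance ceiling (um).
#' @return tibble with `n_pairs`, `n_connected`, `frequency`.
#' @export
connection_frequency <- function(net, pathway = c("fsp", "pp", "pfs"),
                                 d_max = 10) {
  stopifnot(inherits(net, "cortical_net"))
  pathway <- match.arg(pathway)
  pre_c <- switch(pathway, pp = net$p_coords, pfs = net$p_coords,
                  fsp = net$fs_coords)
  post_c <- switch(pathway, pp = net$p_coords, pfs = net$fs_coords,
                   fsp = net$p_coords)
  same <- pathway == "pp"
  pairs <- purrr::map_dfr(seq_len(nrow(pre_c)), function(i) {
    d <- sqrt((post_c$x - pre_c$x[i])^2 + (post_c$y - pre_c$y[i])^2)
    j <- which(d < d_max)
    if (same) j <- setdiff(j, i)
    if (length(j) == 0) return(NULL)
    tibble(pre = i, post = j)
  })
  if (nrow(pairs) == 0) stop("no ordered pairs closer than d_max")
  e <- net$edges[[pathway]]
  connected <- paste(pairs$pre, pairs$post) %in% paste(e$pre, e$post)
  tibble(n_pairs = nrow(pairs), n_connected = sum(connected),
         frequency = mean(connected))
}
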