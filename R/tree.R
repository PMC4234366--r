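#' Read an airway morphometry table
#'
#' Reads a CSV with columns \code{generation}, \code{length_cm},
#' \code{diameter_cm} describing one row per airway generation (0 = trachea).
#' The table must cover a contiguous range of generations starting at 0, all
#' dimensions must be strictly positive, and diameters must be non-increasing
#' with generation.
#'
#' @param path Path to the CSV file.
#' @return A \code{data.frame} with columns \code{generation},
#'   \code{length_cm}, \code{diameter_cm}, ordered by generation.
#' @export
read_morphometry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("generation", "length_cm", "diameter_cm")
  if (!all(required %in% names(tab))) {
    stop("morphometry table must have columns: ", paste(required, collapse = ", "))
  }
  tab <- tab[order(tab$generation), required]
  validate_morphometry(tab)
  tab
}

validate_morphometry <- function(tab) {
  if (!identical(as.integer(tab$generation), seq.int(0L, nrow(tab) - 1L))) {
    stop("morphometry generations must be contiguous 0..G with one row each")
  }
  if (any(tab$length_cm <= 0) || any(tab$diameter_cm <= 0)) {
    stop("morphometry lengths and diameters must be strictly positive")
  }
  if (any(diff(tab$diameter_cm) > 0)) {
    stop("morphometry diameters must be non-increasing with generation")
  }
  invisible(tab)
}

#' Bundled Weibel-style adult morphometry (generations 0-12)
#'
#' Symmetric-tree dimensions for the conducting airways of an adult human
#' lung in the style of Weibel's regular dichotomy model: an 1.8 cm diameter,
#' 12 cm long trachea tapering to sub-millimetre airways at generation 12.
#' Shipped as a versioned CSV under \code{inst/extdata} so users can
#' substitute their own table.
#'
#' @return A morphometry \code{data.frame} (see [read_morphometry()]).
#' @export
default_morphometry <- function() {
  read_morphometry(system.file("extdata", "weibel_morphometry.csv",
                               package = "vdefsim", mustWork = TRUE))
}

#' Build a symmetric bifurcating airway tree
#'
#' Constructs a full binary tree of \code{2^(G+1) - 1} airways over
#' generations \code{0..G}. Airways are numbered breadth-first with the root
#' (trachea) as id 1, so airway \code{i} has children \code{2i} and
#' \code{2i + 1} and the \code{2^G} deepest airways are the terminal airways,
#' each feeding one terminal (acinar) unit. Dimensions are copied per
#' generation from the morphometry table; the wall-thickness factor \code{w}
#' starts at 1 everywhere (see [perturb_wall_thickness()]).
#'
#' @param generations Number of bifurcation generations G (>= 0).
#' @param morphometry Morphometry table covering generations \code{0..G};
#'   defaults to the bundled Weibel-style table.
#' @return An object of class \code{airway_tree}: a list with a per-airway
#'   \code{data.frame} \code{$airways} (columns \code{id}, \code{generation},
#'   \code{parent}, \code{child1}, \code{child2}, \code{length}, \code{r0},
#'   \code{w}, \code{terminal_unit}) plus counts \code{$generations},
#'   \code{$n_airways}, \code{$n_terminal}.
#' @examples
#' tr <- build_tree(3)
#' tr$n_airways   # 15
#' tr$n_terminal  # 8
#' @export
build_tree <- function(generations, morphometry = default_morphometry()) {
  stopifnot(length(generations) == 1L, generations >= 0)
  G <- as.integer(generations)
  validate_morphometry(morphometry)
  if (nrow(morphometry) < G + 1L) {
    stop("morphometry table covers generations 0..", nrow(morphometry) - 1L,
         " but G = ", G, " was requested")
  }
  n <- as.integer(2^(G + 1) - 1)
  id <- seq_len(n)
  gen <- floor(log2(id))
  parent <- ifelse(id == 1L, NA_integer_, id %/% 2L)
  is_term <- gen == G
  child1 <- ifelse(is_term, NA_integer_, 2L * id)
  child2 <- ifelse(is_term, NA_integer_, 2L * id + 1L)
  terminal_unit <- ifelse(is_term, id - 2L^G + 1L, NA_integer_)
  airways <- data.frame(
    id = id,
    generation = as.integer(gen),
    parent = as.integer(parent),
    child1 = as.integer(child1),
    child2 = as.integer(child2),
    length = morphometry$length_cm[gen + 1L],
    r0 = morphometry$diameter_cm[gen + 1L] / 2,
    w = rep(1, n),
    terminal_unit = as.integer(terminal_unit)
  )
  structure(
    list(airways = airways, generations = G,
         n_airways = n, n_terminal = as.integer(2^G)),
    class = "airway_tree"
  )
}

#' @export
print.airway_tree <- function(x, ...) {
  cat("<airway_tree> G =", x$generations, "|", x$n_airways, "airways |",
      x$n_terminal, "terminal units\n")
  cv <- stats::sd(x$airways$w) / mean(x$airways$w)
  cat("  trachea r0 =", format(x$airways$r0[1]), "cm; wall-thickness CV =",
      format(cv, digits = 3), "\n")
  invisible(x)
}

#' Apply random wall-thickness heterogeneity
#'
#' Draws an independent wall-thickness factor \code{w} per airway with mean 1
#' and the requested coefficient of variation. The draw is normal, truncated
#' at 4 standard deviations; non-positive draws (only possible for very large
#' \code{cv}) are redrawn. This small structural heterogeneity perturbs the
#' unstable equilibrium of the perfectly symmetric tree so that ventilation
#' defects can differentiate.
#'
#' @param tree An \code{airway_tree}.
#' @param cv Coefficient of variation of \code{w} (default 0.01).
#' @param seed Integer seed; the same seed reproduces the same factors.
#'   \code{NULL} consumes the current RNG stream instead (used by
#'   [run_simulation()], which seeds one stream per run).
#' @return The tree with its \code{w} column replaced.
#' @export
perturb_wall_thickness <- function(tree, cv = 0.01, seed = 1L) {
  stopifnot(inherits(tree, "airway_tree"), cv >= 0)
  n <- tree$n_airways
  if (cv == 0) {
    tree$airways$w <- rep(1, n)
    return(tree)
  }
  draw_w <- function() {
    draw <- function(k) {
      x <- stats::rnorm(k, mean = 1, sd = cv)
      x[abs(x - 1) > 4 * cv] <- 1 + sign(x[abs(x - 1) > 4 * cv] - 1) * 4 * cv
      x
    }
    x <- draw(n)
    bad <- which(x <= 0)
    while (length(bad) > 0) {
      x[bad] <- draw(length(bad))
      bad <- which(x <= 0)
    }
    x
  }
  tree$airways$w <- if (is.null(seed)) draw_w() else withr_seed(seed, draw_w())
  tree
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Map terminal units onto a rectangular display grid
#'
#' Places the \code{2^G} terminal units on a grid by recursive alternating
#' bisection: the first bifurcation splits the grid with a vertical bisector
#' (child 1 takes the left half), the next level splits each half
#' horizontally (child 1 takes the top half), and so on, one bisection per
#' bifurcation level. Sibling subtrees therefore always occupy the two halves
#' of their parent's rectangle, giving the Mandelbrot-style layout used for
#' ventilation maps (64 x 64 at G = 12).
#'
#' @param tree An \code{airway_tree}.
#' @return An object of class \code{grid_mapping}: list with \code{$nrow},
#'   \code{$ncol} and a \code{data.frame} \code{$cells} of
#'   (\code{unit}, \code{row}, \code{col}), rows/cols 1-based.
#' @export
map_terminals_to_grid <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  G <- tree$generations
  ncol_ <- as.integer(2^ceiling(G / 2))
  nrow_ <- as.integer(2^floor(G / 2))
  units <- seq_len(2L^G)
  path <- units - 1L                     # G-bit path from the root, MSB first
  row <- rep(0L, length(units)); col <- rep(0L, length(units))
  if (G > 0) {
    for (level in seq_len(G)) {
      bit <- bitwAnd(path %/% 2L^(G - level), 1L)
      if (level %% 2L == 1L) col <- 2L * col + bit else row <- 2L * row + bit
    }
  }
  structure(
    list(nrow = nrow_, ncol = ncol_,
         cells = data.frame(unit = units, row = row + 1L, col = col + 1L)),
    class = "grid_mapping"
  )
}

# 1-based ids of the terminal units under airway `id` (BFS numbering).
subtree_terminal_units <- function(tree, id) {
  G <- tree$generations
  gen <- floor(log2(id))
  depth <- G - gen
  first <- id * 2L^depth        # leftmost descendant at generation G
  units <- seq.int(first, first + 2L^depth - 1L) - 2L^G + 1L
  units
}
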