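# Image (MI) and graph (MG) representations of ion pairs.

#' Render the 2D depiction of an ion pair
#'
#' Draws cation and anion together on one square canvas through OpenBabel's
#' 2D depiction engine and returns a grayscale ink raster: 0 = blank canvas,
#' values in (0, 1] where structure is drawn. Deterministic for a given pair
#' and canvas (`image_augment = "off"`).
#'
#' @inheritParams count_fingerprint
#' @return A numeric array `n x image_px x image_px` with values in \[0, 1\].
#' @export
render_image <- function(data, config = featurizer_config()) {
  px <- config$image_px
  n <- nrow(data)
  out <- array(0, dim = c(n, px, px))
  for (i in seq_len(n)) {
    smi <- paste0(data$cation_smiles[i], ".", data$anion_smiles[i])
    out[i, , ] <- ion_pair_raster(smi, px)
  }
  dimnames(out) <- list(data$pair_id, NULL, NULL)
  out
}

ion_pair_raster <- function(smiles, px) {
  key <- paste0("img|", px, "|", smiles)
  cache_get_or(key, function() {
    tf <- tempfile(fileext = ".png")
    on.exit(unlink(tf), add = TRUE)
    ChemmineOB::convertToImage("SMI", "PNG", smiles, toFile = tf,
                               out_options = data.frame(names = "p", args = px))
    p <- png::readPNG(tf)
    if (length(dim(p)) == 3L) p <- apply(p[, , 1:3, drop = FALSE], c(1, 2), mean)
    # white background -> 0 ink; drawn strokes -> positive ink
    m <- 1 - p
    if (nrow(m) != px || ncol(m) != px) {
      stop_value(sprintf("Renderer returned %dx%d, expected %dx%d.",
                         nrow(m), ncol(m), px, px))
    }
    m
  })
}

# Right-angle rotations used for optional training-time augmentation.
rotate_raster <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

# --- molecular graph --------------------------------------------------------

.mg_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Build the molecular graph of an ion pair
#'
#' Nodes are the heavy atoms of cation then anion; node features are the
#' element one-hot (C, N, O, S, P, F, Cl, Br, I, other), degree, formal
#' charge and ring membership; edges are bonds with a bond-order one-hot
#' (single, double, triple) as edge features. No edge crosses the
#' cation/anion boundary.
#'
#' @param pair A one-row tibble with `cation_smiles` and `anion_smiles`
#'   (e.g. from [parse_ion_pair()]), or a list/row of a candidate table.
#' @return A list of class `il_graph`: `nodes` (tibble with `component`,
#'   `element`, `degree`, `charge`, `in_ring`), `edges` (tibble `a1`, `a2`,
#'   `order`), `node_features` (matrix), `edge_features` (matrix).
#' @export
build_graph <- function(pair) {
  cat_mol <- parse_mol(pair$cation_smiles[[1L]])
  an_mol <- parse_mol(pair$anion_smiles[[1L]])
  off <- cat_mol$n_atoms
  nodes <- dplyr::bind_rows(
    dplyr::mutate(cat_mol$atoms, component = "cation"),
    dplyr::mutate(an_mol$atoms, component = "anion")
  )
  edges <- dplyr::bind_rows(
    cat_mol$bonds,
    dplyr::mutate(an_mol$bonds, a1 = a1 + off, a2 = a2 + off)
  )
  elem <- ifelse(nodes$element %in% .mg_elements, nodes$element, "other")
  onehot <- outer(elem, c(.mg_elements, "other"), `==`) * 1
  colnames(onehot) <- paste0("el_", c(.mg_elements, "other"))
  node_features <- cbind(onehot,
                         degree = nodes$degree,
                         charge = nodes$charge,
                         in_ring = as.numeric(nodes$in_ring))
  ord <- pmin(edges$order, 3L)
  edge_features <- outer(ord, 1:3, `==`) * 1
  colnames(edge_features) <- c("single", "double", "triple")
  structure(
    list(nodes = nodes, edges = edges,
         node_features = node_features, edge_features = edge_features,
         pair_id = if ("pair_id" %in% names(pair)) pair$pair_id[[1L]] else NA_character_),
    class = "il_graph"
  )
}

build_graphs <- function(data) {
  lapply(seq_len(nrow(data)), function(i) {
    key <- paste0("graph|", data$cation_smiles[i], ".", data$anion_smiles[i])
    g <- cache_get_or(key, function() build_graph(data[i, , drop = FALSE]))
    g$pair_id <- data$pair_id[i]
    g
  })
}
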