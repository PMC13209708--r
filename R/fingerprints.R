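# Hashed circular (Morgan) fingerprints with bit -> atom-environment maps.
#
# SMILES parsing and perception go through OpenBabel (ChemmineR/ChemmineOB);
# the circular-environment enumeration and hashing are implemented here
# because the atomic-contribution analysis needs, for every set bit, the
# exact heavy atoms whose environments produced it — a map the available
# fingerprint implementations do not expose. Bit positions are deterministic
# but specific to this hash; no cross-toolkit bit compatibility is claimed.

#' Parse SMILES into heavy-atom molecular graphs
#'
#' @param smiles character vector of SMILES strings.
#' @return list of graphs, one per input: `atoms` (data.frame element,
#'   degree), `bonds` (data.frame i, j, order), `n_atoms`.
#' @export
parse_smiles <- function(smiles) {
  if (!length(smiles)) return(list())
  if (any(is.na(smiles) | !nzchar(smiles))) stop("empty or NA SMILES string")
  names(smiles) <- sprintf("m%d", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop(
      "unparseable SMILES among: ",
      paste(utils::head(smiles, 3), collapse = " ; "), " (", conditionMessage(e), ")"
    )
  )
  lapply(seq_along(smiles), function(i) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elem <- sub("_.*$", "", rownames(ab))
    n <- length(elem)
    if (n == 0) stop("SMILES yielded no atoms: ", smiles[i])
    if (is.null(bb) || length(bb) == 0 || is.null(dim(bb)) ||
      nrow(bb) == 0 || ncol(bb) < 3) {
      bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    } else {
      bonds <- data.frame(
        i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
        order = as.integer(bb[, 3])
      )
    }
    degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
    list(
      atoms = data.frame(element = elem, degree = degree, stringsAsFactors = FALSE),
      bonds = bonds,
      n_atoms = n,
      smiles = unname(smiles[i])
    )
  })
}

# deterministic polynomial hash of an integer sequence into [0, 2^31 - 2];
# exact in doubles (intermediates stay far below 2^53)
fp_hash <- function(values) {
  h <- 5381
  for (v in values) h <- (h * 131 + (v %% 2147483647)) %% 2147483647
  h
}

element_number <- function(elem) {
  tab <- c(
    H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
    Cl = 17, Br = 35, I = 53
  )
  z <- tab[elem]
  z[is.na(z)] <- 99 # unrecognized heavy element: single shared code
  unname(z)
}

# all-pairs bond-count distances (Floyd-Warshall; molecules are small)
graph_distances <- function(n, bonds) {
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      dist[bonds$i[b], bonds$j[b]] <- 1
      dist[bonds$j[b], bonds$i[b]] <- 1
    }
    for (k in seq_len(n)) {
      dk <- dist[, k]
      nd <- outer(dk, dist[k, ], `+`)
      upd <- nd < dist
      dist[upd] <- nd[upd]
    }
  }
  dist
}

#' Morgan circular fingerprint with atom-environment map
#'
#' Iteratively hashes each heavy atom's neighborhood out to `radius` bonds
#' (initial invariant: element, heavy degree, summed bond orders; update:
#' radius, own identifier, and the sorted (bond order, neighbor identifier)
#' pairs), folds every environment identifier into `n_bits` hashed bits, and
#' records for each set bit the heavy atoms of every environment that
#' produced it. An environment that stops growing (its atom set equals the
#' previous radius's) is emitted only once, so e.g. methane sets exactly its
#' radius-0 bit.
#'
#' @param smiles a single SMILES string, or a graph from [parse_smiles()].
#' @param radius maximum environment radius in bonds (default 2).
#' @param n_bits fingerprint length, a power of two (default 2048).
#' @return Object of class `morgan_fp`: `bits` (sorted 1-based positions of
#'   set bits), `n_bits`, `bit_atoms` (named list: bit position -> sorted
#'   union of heavy-atom indices over its environments), `environments`
#'   (data.frame atom, radius, bit).
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  if (radius < 0) stop("radius must be >= 0")
  if (n_bits < 2 || bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0) {
    stop("n_bits must be a power of two")
  }
  g <- if (is.character(smiles)) parse_smiles(smiles)[[1]] else smiles
  n <- g$n_atoms
  nbrs <- vector("list", n)
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]
      j <- g$bonds$j[b]
      o <- g$bonds$order[b]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  bond_order_sum <- vapply(seq_len(n), function(a) {
    if (is.null(nbrs[[a]])) 0 else sum(nbrs[[a]][, 2])
  }, numeric(1))
  ids <- vapply(seq_len(n), function(a) {
    fp_hash(c(element_number(g$atoms$element[a]), g$atoms$degree[a], bond_order_sum[a]))
  }, numeric(1))
  dist <- graph_distances(n, g$bonds)
  envs_list <- list(data.frame(atom = seq_len(n), radius = 0L, id = ids))
  prev_size <- rep(1L, n)
  cur_ids <- ids
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      size_r <- vapply(seq_len(n), function(a) sum(dist[a, ] <= r), integer(1))
      new_ids <- vapply(seq_len(n), function(a) {
        if (is.null(nbrs[[a]])) {
          return(cur_ids[a])
        }
        pairs <- nbrs[[a]]
        key <- pairs[, 2] * 2147483647 + cur_ids[pairs[, 1]]
        ord <- order(key)
        fp_hash(c(r, cur_ids[a], as.vector(t(cbind(pairs[ord, 2], cur_ids[pairs[ord, 1]])))))
      }, numeric(1))
      grew <- size_r > prev_size
      if (any(grew)) {
        envs_list[[length(envs_list) + 1]] <- data.frame(
          atom = which(grew), radius = r, id = new_ids[grew]
        )
      }
      prev_size <- size_r
      cur_ids <- new_ids
    }
  }
  envs <- do.call(rbind, envs_list)
  envs$bit <- as.integer(envs$id %% n_bits) + 1L # 1-based bit positions
  bit_atoms <- tapply(seq_len(nrow(envs)), envs$bit, function(rows) {
    sort(unique(unlist(lapply(rows, function(ri) {
      which(dist[envs$atom[ri], ] <= envs$radius[ri])
    }))))
  }, simplify = FALSE)
  bits <- sort(unique(envs$bit))
  structure(list(
    bits = bits,
    n_bits = as.integer(n_bits),
    bit_atoms = bit_atoms[as.character(bits)],
    environments = envs[, c("atom", "radius", "bit")],
    elements = g$atoms$element,
    n_atoms = n,
    radius = as.integer(radius)
  ), class = "morgan_fp")
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat(sprintf(
    "<morgan_fp> %d heavy atoms, radius %d, %d/%d bits set\n",
    x$n_atoms, x$radius, length(x$bits), x$n_bits
  ))
  invisible(x)
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @param radius,n_bits as in [morgan_fingerprint()].
#' @return list: `X` binary matrix (molecules x n_bits), `fps` the per-molecule
#'   `morgan_fp` objects.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 2048) {
  graphs <- parse_smiles(smiles)
  fps <- lapply(graphs, morgan_fingerprint, radius = radius, n_bits = n_bits)
  X <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(fps)) X[i, fps[[i]]$bits] <- 1L
  colnames(X) <- sprintf("bit%04d", seq_len(n_bits))
  list(X = X, fps = fps)
}
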