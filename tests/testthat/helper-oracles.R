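# Independent oracles used to validate the production code paths.
# These deliberately avoid every shortcut the implementation might take:
# the alignment oracle is a cubic-time dynamic program that scores whole
# gap blocks directly (no affine three-matrix bookkeeping), and the
# interface oracle is a plain all-pairs nested-loop distance scan.

# Optimal local alignment score, gap of length k costing open + k * ext.
sw_oracle_score <- function(q, s, mat = NULL, open = 11, ext = 1) {
  if (is.null(mat)) mat <- substitution_matrix("BLOSUM62")
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      v <- max(0, H[i, j] + mat[qc[i], sc[j]])
      for (k in seq_len(i)) v <- max(v, H[i + 1L - k, j + 1L] - (open + k * ext))
      for (k in seq_len(j)) v <- max(v, H[i + 1L, j + 1L - k] - (open + k * ext))
      H[i + 1L, j + 1L] <- max(0, v)
      best <- max(best, v)
    }
  }
  best
}

random_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# All-pairs brute-force interface scan over a parsed structure: explicit
# nested loops, no vectorized distance math, no spatial shortcuts.
brute_force_interfaces <- function(model, cutoff) {
  at <- as.data.frame(model$atoms)
  at <- at[!at$is_hydrogen & !at$is_water, ]
  kinds <- setNames(model$chains$kind, model$chains$chain_id)
  prot <- names(kinds)[kinds == "protein"]

  # entities: polymer chains + each non-polymer residue instance
  ents <- list()
  for (cid in names(kinds)[kinds %in% c("protein", "nucleic")]) {
    ents[[length(ents) + 1L]] <- list(
      id = cid, type = unname(kinds[cid]),
      rows = which(at$chain == cid & at$is_polymer))
  }
  np <- at[!at$is_polymer, ]
  if (nrow(np) > 0L) {
    keys <- unique(np[, c("chain", "resnum", "icode", "resname")])
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      ents[[length(ents) + 1L]] <- list(
        id = paste0(k$chain, "_", k$resname, "_", k$resnum,
                    ifelse(k$icode == "", "", k$icode)),
        type = "ligand",
        rows = which(at$chain == k$chain & at$resnum == k$resnum &
                       at$icode == k$icode & !at$is_polymer))
    }
  }

  recs <- list()
  for (p in prot) {
    prows <- which(at$chain == p & at$is_polymer)
    if (length(prows) == 0L) next
    pres <- unique(at[prows, c("resnum", "icode")])
    for (e in ents) {
      if (e$type %in% c("protein", "nucleic") && e$id == p) next
      for (ri in seq_len(nrow(pres))) {
        rn <- pres$resnum[ri]; ic <- pres$icode[ri]
        arows <- prows[at$resnum[prows] == rn & at$icode[prows] == ic]
        dmin <- Inf
        for (a in arows) for (b in e$rows) {
          d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                      (at$z[a] - at$z[b])^2)
          if (d < dmin) dmin <- d
        }
        if (dmin <= cutoff) {
          recs[[length(recs) + 1L]] <- data.frame(
            chain_id = p, resnum = rn, icode = ic, partner_entity = e$id,
            partner_type = e$type, min_distance = dmin,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0L)
    return(data.frame(chain_id = character(), resnum = integer(),
                      icode = character(), partner_entity = character(),
                      partner_type = character(), min_distance = numeric()))
  do.call(rbind, recs)
}

# Canonical sorted view for set comparison of interface records
iface_key <- function(df) {
  df <- as.data.frame(df)[, c("chain_id", "resnum", "icode",
                              "partner_entity", "partner_type")]
  df <- df[do.call(order, df), ]
  rownames(df) <- NULL
  df
}
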