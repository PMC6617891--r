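## Seeded sequence simulator: two diverged diploid gene pools with
## distinct intron architectures (pool B carries a large intron-4
## deletion; designated B lineages additionally lose intron 5),
## allo- and autotetraploids, intron indels, pseudogenizing exonic
## indels, and full ground truth including the gap-tracked alignment.
##
## Internal representation: a sequence is a triple of parallel vectors
## (keys, bases, seg). Keys are numeric alignment-column identifiers
## inherited from the ancestor; insertions draw fresh keys strictly
## between their neighbours, so the union of keys across sequences
## defines the true multiple alignment. seg labels each base with its
## gene segment ("e4", "i4", ...).

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is designed
#' for: two diploid gene pools separated by 0.08 expected
#' substitutions/site (tip-to-root depth), shallow within-pool
#' divergence (0.02), a 280 bp structural deletion in intron 4 defining
#' pool B's short variant, optional complete intron-5 loss in
#' designated B lineages (the "1c" lineage), intronic indels, and rare
#' 1-2 bp exonic indels creating pseudogenes.
#'
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param nDiploidsA,nDiploidsB diploid individuals per pool.
#' @param nAllo,nAuto tetraploid individuals formed by cross-pool
#'   hybridization + doubling vs within-pool doubling.
#' @param stemDepth tip-to-root depth (expected substitutions/site);
#'   the expected between-pool path length is \code{2 * stemDepth}.
#' @param crownDepth within-pool terminal branch length; must not
#'   exceed \code{stemDepth}.
#' @param exonRateScale relative substitution rate of exon sites
#'   (default 0.2): purifying selection slows coding sequence relative
#'   to introns, which evolve at the nominal JC69 rate; the default
#'   keeps congeneric amino-acid identity in the mid-90s as typical
#'   for a conserved enzyme.
#' @param intronIndelRate expected indel events per intron per branch.
#' @param indelLenMean geometric mean indel length (bp).
#' @param intron4DeletionBp structural deletion applied on pool B's
#'   stem (default 280).
#' @param intron5LossIn integer indices of pool-B diploid lineages that
#'   lose intron 5 entirely (default none).
#' @param pseudogeneRate per-sequence probability of a 1-2 bp exonic
#'   indel.
#' @param polyploidTipDepth terminal branch length of each polyploid
#'   gene copy below its parent lineage (default 0.004: polyploid
#'   formation recent relative to the within-pool crown, yet old
#'   enough that each copy branch carries substitutions).
#' @param includeOutgroup add one outgroup sequence for rooting.
#' @param outgroupDepth branch length of the outgroup from the root.
#' @param ref the ancestral \linkS4class{ReferenceModel}.
#' @return list of class "SimConfig".
#' @export
simConfig <- function(seed = 1L, nDiploidsA = 10L, nDiploidsB = 10L,
                      nAllo = 5L, nAuto = 5L, stemDepth = 0.08,
                      crownDepth = 0.02, exonRateScale = 0.2,
                      intronIndelRate = 0.3,
                      indelLenMean = 8, intron4DeletionBp = 280L,
                      intron5LossIn = integer(), pseudogeneRate = 0.03,
                      polyploidTipDepth = 0.004, includeOutgroup = TRUE,
                      outgroupDepth = 0.15, ref = syntheticReference()) {
  if (stemDepth < 0 || crownDepth < 0 || intronIndelRate < 0 ||
      pseudogeneRate < 0 || polyploidTipDepth < 0) {
    hpStop("hp_config_error", "rates and depths must be non-negative")
  }
  if (crownDepth > stemDepth) {
    hpStop("hp_config_error", "crownDepth must not exceed stemDepth")
  }
  if (polyploidTipDepth > crownDepth) {
    hpStop("hp_config_error", "polyploidTipDepth must not exceed crownDepth")
  }
  if (nDiploidsA < 2L || nDiploidsB < 2L) {
    hpStop("hp_config_error", "each pool needs at least two diploid lineages")
  }
  refI4 <- intronLengths(refModel(ref))[["4"]]
  if (intron4DeletionBp >= refI4 - 4L) {
    hpStop("hp_config_error",
           "intron4DeletionBp (%d) must leave the %d bp ancestral intron 4 intact at its splice sites",
           intron4DeletionBp, refI4)
  }
  if (length(intron5LossIn) && (min(intron5LossIn) < 1L ||
                                max(intron5LossIn) > nDiploidsB)) {
    hpStop("hp_config_error", "intron5LossIn must index pool-B lineages")
  }
  structure(list(seed = seed, nDiploidsA = nDiploidsA,
                 nDiploidsB = nDiploidsB, nAllo = nAllo, nAuto = nAuto,
                 stemDepth = stemDepth, crownDepth = crownDepth,
                 exonRateScale = exonRateScale,
                 intronIndelRate = intronIndelRate,
                 indelLenMean = indelLenMean,
                 intron4DeletionBp = as.integer(intron4DeletionBp),
                 intron5LossIn = as.integer(intron5LossIn),
                 pseudogeneRate = pseudogeneRate,
                 polyploidTipDepth = polyploidTipDepth,
                 includeOutgroup = includeOutgroup,
                 outgroupDepth = outgroupDepth, ref = ref),
            class = "SimConfig")
}

## ---- sequence-state primitives -----------------------------------------

stateFromReference <- function(ref) {
  sq <- strsplit(as.character(refSequence(ref)), "", fixed = TRUE)[[1]]
  seg <- geneSegments(refModel(ref))
  lab <- sprintf("%s%d", ifelse(seg$kind == "exon", "e", "i"), seg$index)
  segv <- rep(lab, seg$end - seg$start)
  list(keys = as.numeric(seq_along(sq)), bases = sq, seg = segv)
}

## positions (indices into the state) protected from mutation:
## the first and last two bases of every intron (splice dinucleotides).
protectedIdx <- function(state) {
  r <- rle(state$seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(0)
  for (k in which(startsWith(r$values, "i") & r$lengths >= 4L)) {
    idx <- c(idx, starts[k], starts[k] + 1L, ends[k] - 1L, ends[k])
  }
  idx
}

## indices eligible for intron indels: intron interiors (>= 2 bases away
## from both segment ends).
intronInterior <- function(state, segLabel) {
  pos <- which(state$seg == segLabel)
  if (length(pos) <= 4L) return(integer(0))
  pos[seq(3L, length(pos) - 2L)]
}

exonIdx <- function(state) which(startsWith(state$seg, "e"))

## JC69 substitutions plus stop-codon avoidance in exons. Exon sites
## substitute at `exonScale` times the nominal rate.
substituteBranch <- function(state, t, exonScale = 1) {
  if (t <= 0) return(state)
  n <- length(state$bases)
  p <- rep(0.75 * (1 - exp(-4 * t / 3)), n)
  isExon <- startsWith(state$seg, "e")
  p[isExon] <- 0.75 * (1 - exp(-4 * t * exonScale / 3))
  hit <- runif(n) < p
  hit[protectedIdx(state)] <- FALSE
  if (!any(hit)) return(state)
  old <- state$bases
  bases <- c("A", "C", "G", "T")
  ix <- which(hit)
  cur <- match(state$bases[ix], bases)
  step <- sample.int(3L, length(ix), replace = TRUE)
  state$bases[ix] <- bases[((cur - 1L + step) %% 4L) + 1L]
  ## purifying selection: revert any substitution creating an in-frame
  ## stop codon in the exonic reading frame
  ex <- exonIdx(state)
  nCod <- length(ex) %/% 3L
  if (nCod > 0L) {
    codIdx <- matrix(ex[seq_len(nCod * 3L)], nrow = 3L)
    cod <- paste0(state$bases[codIdx[1L, ]], state$bases[codIdx[2L, ]],
                  state$bases[codIdx[3L, ]])
    bad <- which(cod %in% c("TAA", "TAG", "TGA"))
    for (b in bad) state$bases[codIdx[, b]] <- old[codIdx[, b]]
  }
  state
}

deleteAt <- function(state, idx) {
  if (!length(idx)) return(state)
  state$keys <- state$keys[-idx]
  state$bases <- state$bases[-idx]
  state$seg <- state$seg[-idx]
  state
}

insertAfter <- function(state, pos, bases, segLabel) {
  k1 <- state$keys[pos]
  k2 <- state$keys[pos + 1L]
  newKeys <- sort(runif(length(bases), k1, k2))
  list(keys = append(state$keys, newKeys, after = pos),
       bases = append(state$bases, bases, after = pos),
       seg = append(state$seg, rep(segLabel, length(bases)), after = pos))
}

## intron indels on one branch: Poisson(rate) events per intron.
intronIndelsBranch <- function(state, cfg) {
  for (seg in unique(state$seg[startsWith(state$seg, "i")])) {
    nEv <- stats::rpois(1L, cfg$intronIndelRate)
    for (ev in seq_len(nEv)) {
      interior <- intronInterior(state, seg)
      if (length(interior) < 2L) next
      len <- stats::rgeom(1L, 1 / cfg$indelLenMean) + 1L
      if (runif(1) < 0.5) {  # deletion
        startPos <- interior[sample.int(length(interior), 1L)]
        last <- min(startPos + len - 1L, interior[length(interior)])
        state <- deleteAt(state, startPos:last)
      } else {               # insertion
        pos <- interior[sample.int(length(interior), 1L)]
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        state <- insertAfter(state, pos, ins, seg)
      }
    }
  }
  state
}

evolveBranch <- function(state, t, cfg) {
  state <- substituteBranch(state, t, cfg$exonRateScale)
  if (cfg$intronIndelRate > 0) state <- intronIndelsBranch(state, cfg)
  state
}

## structural deletion of `bp` bases from the centre of an intron
deleteIntronCenter <- function(state, segLabel, bp) {
  interior <- intronInterior(state, segLabel)
  if (length(interior) < bp) {
    hpStop("hp_config_error", "structural deletion exceeds intron %s", segLabel)
  }
  mid <- (length(interior) - bp) %/% 2L
  deleteAt(state, interior[(mid + 1L):(mid + bp)])
}

loseIntron <- function(state, segLabel) {
  deleteAt(state, which(state$seg == segLabel))
}

## 1-2 bp exonic indel (pseudogenization); always frameshifting.
## Candidate positions keep the whole event inside one exon, away from
## its boundaries, so splice sites and projection stay unaffected.
pseudogenize <- function(state) {
  len <- sample.int(2L, 1L)
  cand <- integer(0)
  for (sg in unique(state$seg[startsWith(state$seg, "e")])) {
    pos <- which(state$seg == sg)
    if (length(pos) < len + 4L) next
    cand <- c(cand, pos[seq(3L, length(pos) - len - 1L)])
  }
  pos <- cand[sample.int(length(cand), 1L)]
  if (runif(1) < 0.5) {
    deleteAt(state, pos:(pos + len - 1L))
  } else {
    insertAfter(state, pos, sample(c("A", "C", "G", "T"), len, replace = TRUE),
                state$seg[pos])
  }
}

## ---- the generator ------------------------------------------------------

#' Simulate a homoeolog dataset with ground truth
#'
#' See \code{\link{simConfig}} for the generative model. All
#' randomness is governed by \code{cfg$seed}; the caller's RNG state is
#' left untouched.
#'
#' @param cfg a \code{simConfig()}.
#' @return list of class "SimResult": \code{sequences} (unaligned
#'   DNAStringSet), \code{meta} (metadata data.frame),
#'   \code{truth} (class "SimTruth": \code{perSequence},
#'   \code{perIndividual}, \code{alignment} (character matrix),
#'   \code{columns} (key/segment/protected per column), \code{tree}
#'   (the generating \code{phylo})), and \code{config}.
#' @export
simulateDataset <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(cfg$seed, {
    root <- stateFromReference(cfg$ref)
    stemBranch <- cfg$stemDepth - cfg$crownDepth

    seqs <- list(); truthRows <- list(); indRows <- list()
    emit <- function(state, seqId, indId, pool, variant, pathLen) {
      ## pseudogenization decided at emission
      pseudo <- runif(1) < cfg$pseudogeneRate
      if (pseudo) state <- pseudogenize(state)
      seqs[[seqId]] <<- state
      truthRows[[seqId]] <<- data.frame(
        seq_id = seqId, individual_id = indId, pool = pool,
        variant_truth = variant, pseudogene = pseudo,
        path_length = pathLen)
      invisible(NULL)
    }

    ancA <- evolveBranch(root, stemBranch, cfg)
    ancB <- deleteIntronCenter(evolveBranch(root, stemBranch, cfg),
                               "i4", cfg$intron4DeletionBp)

    ## within-pool crown genealogies: random ultrametric trees whose
    ## joins fall in the upper part of the crown, so the radiation is
    ## bifurcating (no true polytomies), every sampled lineage has a
    ## long terminal branch onto which polyploid parent lineages can
    ## attach with individually resolvable edges, and within-pool tip
    ## divergence is on the order of crownDepth
    randomCrownTree <- function(n, depth, tipLabels) {
      hs <- sort(runif(n - 1L, 0.7 * depth, depth))
      hs[n - 1L] <- depth
      frags <- tipLabels
      hgt <- rep(0, n)
      for (h in hs) {
        pick <- sample.int(length(frags), 2L)
        f <- sprintf("(%s:%.8g,%s:%.8g)", frags[pick[1L]], h - hgt[pick[1L]],
                     frags[pick[2L]], h - hgt[pick[2L]])
        frags <- c(frags[-pick], f)
        hgt <- c(hgt[-pick], h)
      }
      ape::read.tree(text = paste0(frags, ";"))
    }
    poolTrees <- list()
    for (pool in c("A", "B")) {
      nD <- if (pool == "A") cfg$nDiploidsA else cfg$nDiploidsB
      tr <- randomCrownTree(nD, cfg$crownDepth,
                            sprintf("d%s%02d__1", pool, seq_len(nD)))
      poolTrees[[pool]] <- stats::reorder(tr, "cladewise")
    }
    termLen <- function(tr, tip) tr$edge.length[match(tip, tr$edge[, 2])]

    ## polyploid parental gene lineages diverge from within each pool's
    ## sampled radiation: each parent is sister to one sampled diploid
    ## lineage, splitting from its terminal branch at a height tau
    ## above the tips. tau is kept at or above twice the polyploid age
    ## where the branch allows, so the copy pair coalesces clearly
    ## below the parent's divergence from its sampled sister.
    att <- list(A = rep(list(list()), cfg$nDiploidsA),
                B = rep(list(list()), cfg$nDiploidsB))
    attachLog <- list()
    addAttachment <- function(pool, indId, copyIds) {
      nD <- if (pool == "A") cfg$nDiploidsA else cfg$nDiploidsB
      tr <- poolTrees[[pool]]
      tb <- vapply(seq_len(nD), function(i) termLen(tr, i), numeric(1))
      cand <- which(tb > 2.5 * cfg$polyploidTipDepth)
      i <- if (length(cand)) cand[sample.int(length(cand), 1L)]
           else which.max(tb)
      ## stay well inside the terminal branch (the parent's divergence
      ## must be clearly younger than its sister lineage's own
      ## divergence) and clearly above the copy coalescence, so the
      ## three events bounding the attachment each leave a resolvable
      ## number of substitutions
      hi <- 0.75 * tb[i]
      lo <- min(max(2 * cfg$polyploidTipDepth, hi / 2), 0.9 * hi)
      tau <- runif(1, lo, hi)
      att[[pool]][[i]] <<- c(att[[pool]][[i]],
                             list(list(indId = indId, copyIds = copyIds,
                                       tau = tau)))
      attachLog[[length(attachLog) + 1L]] <<- data.frame(
        individual_id = indId, pool = pool,
        sister_tip = sprintf("d%s%02d__1", pool, i), tau = tau,
        sister_branch = tb[i])
      invisible(NULL)
    }
    for (k in seq_len(cfg$nAllo)) {
      indId <- sprintf("allo%02d", k)
      addAttachment("A", indId, sprintf("%s__1", indId))
      addAttachment("B", indId, sprintf("%s__2", indId))
      indRows[[indId]] <- data.frame(individual_id = indId, ploidy = 4L,
                                     origin_mode = "allopolyploid",
                                     section = "Malachobatus")
    }
    for (k in seq_len(cfg$nAuto)) {
      indId <- sprintf("auto%02d", k)
      pool <- sample(c("A", "B"), 1L)
      addAttachment(pool, indId, sprintf("%s__%d", indId, 1:2))
      indRows[[indId]] <- data.frame(individual_id = indId, ploidy = 4L,
                                     origin_mode = "autopolyploid",
                                     section = "Malachobatus")
    }

    ## evolve along each pool tree; on terminal branches peel off the
    ## attached parent lineages at their heights; collect per-tip
    ## newick fragments (each includes its full terminal-edge
    ## structure and outer branch length)
    poolFrags <- list()
    for (pool in c("A", "B")) {
      tr <- poolTrees[[pool]]
      ntip <- length(tr$tip.label)
      anc <- if (pool == "A") ancA else ancB
      baseVariant <- if (pool == "A") "1a" else "1b"
      states <- vector("list", ntip + tr$Nnode)
      states[[ntip + 1L]] <- anc
      tipFrag <- character(ntip)
      for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        len <- tr$edge.length[e]
        if (ch > ntip) {
          states[[ch]] <- evolveBranch(states[[par]], len, cfg)
          next
        }
        i <- ch
        A <- att[[pool]][[i]]
        taus <- vapply(A, function(a) a$tau, numeric(1))
        ord <- order(-taus)
        cur <- states[[par]]
        h <- len                 # height above this tip
        parFrags <- character(length(ord))
        for (jj in seq_along(ord)) {
          a <- A[[ord[jj]]]
          cur <- evolveBranch(cur, h - a$tau, cfg)
          h <- a$tau
          ## the copy pair coalesces at most half-way up its parent
          ## lineage, so pair coalescence and parent divergence are
          ## distinct, resolvable events
          pt <- min(cfg$polyploidTipDepth, a$tau / 2)
          parState <- evolveBranch(cur, a$tau - pt, cfg)
          for (cid in a$copyIds) {
            st <- evolveBranch(parState, pt, cfg)
            emit(st, cid, a$indId, pool, baseVariant, cfg$stemDepth)
          }
          parFrags[jj] <- if (length(a$copyIds) == 1L) {
            sprintf("%s:%.6g", a$copyIds, a$tau)
          } else {
            sprintf("(%s):%.6g",
                    paste(sprintf("%s:%.6g", a$copyIds, pt), collapse = ","),
                    a$tau - pt)
          }
        }
        tipState <- evolveBranch(cur, h, cfg)
        variant <- baseVariant
        if (pool == "B" && i %in% cfg$intron5LossIn) {
          tipState <- loseIntron(tipState, "i5")
          variant <- "1c"
        }
        indId <- sprintf("d%s%02d", pool, i)
        seqId <- paste0(indId, "__1")
        emit(tipState, seqId, indId, pool, variant, cfg$stemDepth)
        indRows[[indId]] <- data.frame(individual_id = indId, ploidy = 2L,
                                       origin_mode = "diploid",
                                       section = "Idaeobatus")
        frag <- sprintf("%s:%.6g", seqId,
                        if (length(ord)) taus[ord[length(ord)]] else len)
        for (jj in rev(seq_along(ord))) {
          upper <- if (jj > 1L) taus[ord[jj - 1L]] else len
          frag <- sprintf("(%s,%s):%.6g", frag, parFrags[jj],
                          upper - taus[ord[jj]])
        }
        tipFrag[i] <- frag
      }
      ## assemble the pool newick recursively over internal nodes
      rec <- function(node) {
        kids <- tr$edge[tr$edge[, 1L] == node, 2L]
        parts <- vapply(kids, function(ch) {
          if (ch <= ntip) return(tipFrag[ch])
          len <- tr$edge.length[match(ch, tr$edge[, 2L])]
          sprintf("(%s):%.6g", rec(ch), len)
        }, character(1))
        paste(parts, collapse = ",")
      }
      poolFrags[[pool]] <- rec(ntip + 1L)
    }

    ## two outgroup taxa forming their own small clade: rooting on a
    ## two-tip outgroup is far more stable than on one long branch
    ogCrown <- min(cfg$crownDepth, cfg$outgroupDepth / 2)
    if (cfg$includeOutgroup) {
      ogAnc <- evolveBranch(root, cfg$outgroupDepth - ogCrown, cfg)
      for (j in 1:2) {
        st <- evolveBranch(ogAnc, ogCrown, cfg)
        indId <- sprintf("OUT%02d", j)
        emit(st, paste0(indId, "__1"), indId, "outgroup", "outgroup",
             cfg$outgroupDepth)
        indRows[[indId]] <- data.frame(individual_id = indId, ploidy = 2L,
                                       origin_mode = "outgroup",
                                       section = "Outgroup")
      }
    }

    ## generating tree (newick)
    ingroup <- sprintf("((%s):%.6g,(%s):%.6g)", poolFrags[["A"]], stemBranch,
                       poolFrags[["B"]], stemBranch)
    nw <- if (cfg$includeOutgroup) {
      sprintf("((OUT01__1:%.6g,OUT02__1:%.6g):%.6g,%s:0);",
              ogCrown, ogCrown, cfg$outgroupDepth - ogCrown, ingroup)
    } else paste0(ingroup, ";")
    tree <- ape::read.tree(text = nw)

    ## truth alignment from the union of keys
    allKeys <- sort(unique(unlist(lapply(seqs, `[[`, "keys"))))
    alnM <- matrix("-", nrow = length(seqs), ncol = length(allKeys),
                   dimnames = list(names(seqs), NULL))
    colSeg <- rep(NA_character_, length(allKeys))
    for (s in names(seqs)) {
      ix <- match(seqs[[s]]$keys, allKeys)
      alnM[s, ix] <- seqs[[s]]$bases
      colSeg[ix] <- seqs[[s]]$seg
    }
    ## protected columns: ancestral splice dinucleotides
    prot <- protectedIdx(stateFromReference(cfg$ref))
    columns <- data.frame(key = allKeys, segment = colSeg,
                          protected = allKeys %in% prot)

    meta <- do.call(rbind, indRows)
    meta$taxon_name <- paste0("sim_taxon_", meta$individual_id)
    meta$subsection <- ""
    accBySeq <- split(names(seqs),
                      sub("__.*$", "", names(seqs)))
    meta$accessions <- vapply(meta$individual_id, function(id)
      paste(sort(accBySeq[[id]]), collapse = ";"), character(1))
    meta <- meta[, c("individual_id", "taxon_name", "section", "subsection",
                     "ploidy", "accessions", "origin_mode")]
    rownames(meta) <- NULL

    perSequence <- do.call(rbind, truthRows[names(seqs)])
    rownames(perSequence) <- NULL
    perIndividual <- do.call(rbind, indRows)
    rownames(perIndividual) <- NULL

    dss <- Biostrings::DNAStringSet(vapply(seqs, function(s)
      paste(s$bases, collapse = ""), character(1)))
    names(dss) <- names(seqs)

    truth <- structure(list(perSequence = perSequence,
                            perIndividual = perIndividual,
                            alignment = alnM, columns = columns,
                            tree = tree,
                            attachments = if (length(attachLog))
                              do.call(rbind, attachLog) else NULL),
                       class = "SimTruth")
    structure(list(sequences = dss, meta = meta, truth = truth,
                   config = cfg),
              class = "SimResult")
  })
}

#' Flat delimited report of simulation ground truth
#'
#' One row per emitted sequence, joined with its individual's origin
#' mode and ploidy; writing the table and reading it back reproduces
#' the same rows.
#'
#' @param truth a "SimTruth" (from \code{simulateDataset()$truth}).
#' @return data.frame.
#' @export
truthReport <- function(truth) {
  ps <- truth$perSequence
  if (is.null(ps) || nrow(ps) == 0L) {
    return(data.frame(seq_id = character(), individual_id = character(),
                      pool = character(), variant_truth = character(),
                      pseudogene = logical(), path_length = numeric(),
                      ploidy = integer(), origin_mode = character()))
  }
  mrow <- match(ps$individual_id, truth$perIndividual$individual_id)
  cbind(ps, ploidy = truth$perIndividual$ploidy[mrow],
        origin_mode = truth$perIndividual$origin_mode[mrow])
}
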