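# Builds the bundled synthetic representative GUS set (run from the
# package root):
#   inst/extdata/synthetic_representatives.faa / .tsv
# 17 representatives over the structural classes, sharing a common core
# scaffold (~38-50% mutual identity) with class-specific loop-1/loop-2
# segment lengths, 7 invariant catalytic positions, and a conserved
# C-terminal FMN-binding domain for the FMN class.
library(gusome)

set.seed(777001)
AA <- c(A=8.3,C=1.4,D=5.4,E=6.8,F=3.9,G=7.1,H=2.3,I=6.0,K=5.8,L=9.7,M=2.4,
        N=4.1,P=4.7,Q=3.9,R=5.5,S=6.6,T=5.3,V=6.9,W=1.1,Y=2.9)
rnd <- function(n) sample(names(AA), n, TRUE, prob = AA)

core_len <- 340; segB_len <- 60; segC_len <- 40; fmn_len <- 60
cat_pos <- c(160, 162, 205, 248, 310, 330, 338)
cat_res <- c("N", "K", "Y", "E", "E", "N", "H")

base_core <- rnd(core_len); base_core[cat_pos] <- cat_res
base_segB <- rnd(segB_len); base_segC <- rnd(segC_len)
base_fmn  <- rnd(fmn_len)

loop_len <- list(L1 = c(18, 2), mL1 = c(8, 2), L2 = c(2, 16), mL2 = c(2, 8),
                 mL1_2 = c(8, 8), NL = c(2, 2), FMN = c(2, 2))
plan <- c(rep("L1", 4), rep("mL1", 3), rep("L2", 2), rep("mL2", 2),
          "mL1_2", rep("NL", 3), rep("FMN", 2))
taxa <- c("Bacteroides simulans", "Bacteroides fictus", "Phocaeicola modelli",
          "Parabacteroides exemplar", "Lactobacillus artificialis",
          "Blautia synthetica", "Roseburia imitata", "Bacteroides simulans",
          "Alistipes confectus", "Clostridium fabricatum",
          "Eubacterium simulatum", "Dorea conficta", "Faecalibacterium fictum",
          "Ruminococcus artifex", "Coprococcus exemplaris",
          "Roseburia imitata", "Faecalibacterium fictum")

mutate_core <- function(chars, rate, keep = integer()) {
  idx <- setdiff(seq_along(chars), keep)
  hit <- idx[runif(length(idx)) < rate]
  chars[hit] <- vapply(chars[hit],
                       function(a) sample(setdiff(names(AA), a), 1), "")
  chars
}

rows <- list(); seqs <- character()
for (i in seq_along(plan)) {
  cls <- plan[i]
  ll <- loop_len[[cls]]
  core <- mutate_core(base_core, 0.35, cat_pos)
  segB <- mutate_core(base_segB, 0.35)
  segC <- mutate_core(base_segC, 0.35)
  loop1 <- rnd(ll[1]); loop2 <- rnd(ll[2])
  parts <- c(core, loop1, segB, loop2, segC)
  fmn_iv <- c(NA, NA)
  if (cls == "FMN") {
    fmn_dom <- mutate_core(base_fmn, 0.10)   # conserved FMN-binding domain
    parts <- c(parts, fmn_dom)
    fmn_iv <- c(length(parts) - fmn_len + 1, length(parts))
  }
  seq <- paste(parts, collapse = "")
  id <- sprintf("synthRep%02d_%s", i, cls)
  l1s <- core_len + 1; l1e <- core_len + ll[1]
  l2s <- core_len + ll[1] + segB_len + 1; l2e <- l2s + ll[2] - 1
  seqs[id] <- seq
  rows[[i]] <- data.frame(
    id = id, gus_class = cls, taxonomy = taxa[i],
    catalytic = paste(sprintf("%d:%s", cat_pos, cat_res), collapse = ","),
    loop1_start = l1s, loop1_end = l1e, loop2_start = l2s, loop2_end = l2e,
    fmn_start = fmn_iv[1], fmn_end = fmn_iv[2], stringsAsFactors = FALSE)
}
ann <- do.call(rbind, rows)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_protein_fasta(data.frame(id = names(seqs), seq = unname(seqs),
                               stringsAsFactors = FALSE),
                    "inst/extdata/synthetic_representatives.faa")
write_table(ann, "inst/extdata/synthetic_representatives.tsv")

# --- verification against the package's own readers/classifier ---
reps <- read_representatives("inst/extdata/synthetic_representatives.faa",
                             "inst/extdata/synthetic_representatives.tsv")
p <- alignment_params()
ids <- sapply(reps, function(a) sapply(reps, function(b)
  pairwise_identity(a$seq, b$seq, p)))
cat("pairwise identity range (off-diagonal):",
    round(range(ids[upper.tri(ids)]), 3), "\n")
ok <- vapply(reps, function(r)
  assign_class(r$seq, reps, params = p)$gus_class == r$gus_class, TRUE)
cat("self-classification correct:", sum(ok), "/", length(ok), "\n")
if (!all(ok)) print(names(ok)[!ok])
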