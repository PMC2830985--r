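# Generates the packaged text fixtures under inst/extdata/ from a single
# transcription of the published interaction tables (one per hematopoietic
# population).  Run from the repository root:  Rscript data-raw/make_fixtures.R
#
# Everything downstream (per-table expression profiles, per-table stroma and
# comparator profiles, expected interaction tables, the pair database, the
# gene registry) is projected from the `tables` object below, so the
# transcription exists in exactly one place.

registry <- read.table(header = TRUE, sep = ";", strip.white = TRUE,
                       stringsAsFactors = FALSE, quote = "", text = "
symbol; gene; role; description
Acvr1; 11477; receptor; activin A receptor, type 1
Acvr2a; 11480; receptor; activin receptor IIA
Acvr2b; 11481; receptor; activin receptor IIB
Bmp15; 12155; ligand; Bone morphogenetic protein 15
Bmp4; 12159; ligand; bone morphogenetic protein 4
Bmpr1a; 12166; receptor; bone morphogenetic protein receptor, type 1A
Ccl2; 20296; ligand; chemokine (C-C motif) ligand 2
Ccl25; 20300; ligand; chemokine (C-C motif) ligand 25
Ccr2; 12772; receptor; chemokine (C-C motif) receptor 2
Ccr9; 12769; receptor; chemokine (C-C motif) receptor 9
Cd28; 12487; receptor; CD28 antigen
Cd80; 12519; ligand; CD80 antigen
Cxcl12; 20315; ligand; chemokine (C-X-C motif) ligand 12
Cxcr4; 12767; receptor; chemokine (C-X-C motif) receptor 4
Egfr; 13649; receptor; epidermal growth factor receptor
Ereg; 13874; ligand; epiregulin
Igf2; 16002; ligand; insulin-like growth factor 2
Igf2r; 16004; receptor; insulin-like growth factor 2 receptor
Il1r1; 16177; receptor; interleukin 1 receptor, type I
Il1r2; 16178; receptor; interleukin 1 receptor, type II
Il1rn; 16181; ligand; interleukin 1 receptor antagonist
Il2rg; 16186; receptor; interleukin 2 receptor, gamma chain
Il7; 16196; ligand; interleukin 7
Itga4; 16401; adhesion; Integrin alpha 4
Itgb1; 16412; adhesion; integrin beta 1 (fibronectin receptor beta)
Itgb2; 16414; adhesion; integrin beta 2
Itgb7; 16421; adhesion; integrin beta 7
Jag2; 16450; ligand; jagged 2
Jam2; 67374; adhesion; junction adhesion molecule 2
Jam3; 83964; adhesion; junction adhesion molecule 3
Kdr; 16542; receptor; kinase insert domain protein receptor
L1cam; 16728; adhesion; L1 cell adhesion molecule
Lta; 16992; ligand; lymphotoxin A
Ltbr; 17000; receptor; lymphotoxin B receptor
Ncam1; 17967; adhesion; neural cell adhesion molecule 1
Notch3; 18131; receptor; Notch gene homolog 3 (Drosophila)
Nrp1; 18186; receptor; neuropilin 1
Odc-rs; 70458; unknown; Similar to Ornithine decarboxylase (ODC)
Osm; 18413; ligand; oncostatin M
Osmr; 18414; receptor; oncostatin M receptor
Pdgfb; 18591; ligand; platelet derived growth factor, B polypeptide
Pdgfra; 18595; receptor; platelet derived growth factor receptor, alpha polypeptide
Pdgfrb; 18596; receptor; platelet derived growth factor receptor, beta polypeptide
Tgfa; 21802; ligand; transforming growth factor alpha
Tgfb1; 21803; ligand; transforming growth factor, beta 1
Tgfbr2; 21813; receptor; transforming growth factor, beta receptor II
Tgfbr3; 21814; receptor; transforming growth factor, beta receptor III
Tnf; 21926; ligand; tumor necrosis factor
Tnfrsf1a; 21937; receptor; tumor necrosis factor receptor superfamily, member 1a
Tnfrsf1b; 21938; receptor; tumor necrosis factor receptor superfamily, member 1b
Vcam1; 22329; adhesion; vascular cell adhesion molecule 1
Vegfa; 22339; ligand; vascular endothelial growth factor A
Vegfb; 22340; ligand; vascular endothelial growth factor B
")
registry$gene <- as.character(registry$gene)

# One row per printed table line: population symbol/intensity, stroma
# symbol/intensity, NIH3T3 and MC3T3 (osteoblast) comparator intensities.
tab <- function(txt) {
  read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
             stringsAsFactors = FALSE, text = txt,
             col.names = c("pop_symbol", "pop_intensity", "stroma_symbol",
                           "stroma_intensity", "NIH3T3", "MC3T3"))
}

tables <- list(
  lthsc = tab("
p;pi;s;si;n;o
Acvr2b;267;Bmp4;1335;66;252
Bmp4;169;Bmpr1a;497;274;384
Cxcr4;372;Cxcl12;12222;23;798
Egfr;149;Ereg;422;288;153
Igf2;105;Igf2r;535;1772;1704
Itga4;1675;Jam2;201;16;26
Itgb1;307;Jam2;201;16;26
Itgb2;558;Jam3;152;42;204
Jag2;222;Notch3;367;161;48
Osm;115;Osmr;1151;1349;131
Egfr;149;Tgfa;261;13;21
Itga4;1675;Vcam1;692;182;929
Itgb1;307;Vcam1;692;182;929
Itgb7;329;Vcam1;692;182;929
Kdr;311;Vegfa;179;1006;169
"),
  mpp = tab("
p;pi;s;si;n;o
Acvr2b;183;Bmp4;1335;66;252
Bmp15;413;Bmpr1a;327;377;287
Bmp4;112;Bmpr1a;327;377;287
Cxcr4;264;Cxcl12;12222;23;798
Egfr;231;Ereg;422;288;153
Igf2;271;Igf2r;535;1772;1704
Il1r1;123;Il1rn;3515;16;10
Itga4;278;Jam2;201;16;26
Itgb1;180;Jam2;201;16;26
Itgb2;507;Jam3;152;42;204
Osm;157;Osmr;1151;1349;131
Egfr;231;Tgfa;261;13;21
Itga4;278;Vcam1;692;182;929
Itgb1;180;Vcam1;692;182;929
"),
  lmpp = tab("
p;pi;s;si;n;o
Acvr2a;131;Bmp4;1335;66;252
Acvr1;107;Bmp4;1335;66;252
Bmp4;277;Bmpr1a;497;274;384
Egfr;189;Ereg;422;288;153
Igf2;139;Igf2r;535;1772;1704
Il2rg;2115;Il7;189;92;255
Osm;178;Osmr;1151;1349;131
Cxcr4;290;Cxcl12;12222;23;798
Egfr;189;Tgfa;261;13;21
Tnf;102;Tnfrsf1a;1974;959;1143
Tnf;102;Tnfrsf1b;108;721;108
Itga4;268;Vcam1;692;182;929
Itgb7;453;Vcam1;692;182;929
Itgb1;173;Vcam1;692;182;929
Itgb1;173;Jam2;201;16;26
Itga4;268;Jam2;201;16;26
Itgb2;484;Jam3;152;42;204
"),
  clp = tab("
p;pi;s;si;n;o
Il2rg;3021;Il7;189;92;255
Cxcr4;2121;Cxcl12;12222;23;798
Itga4;1982;Vcam1;692;182;929
Itga4;1982;Jam2;201;16;26
Itgb2;920;Jam3;152;42;204
Bmp15;645;Bmpr1a;497;274;384
Ccr9;443;Ccl25;123;55;100
Igf2;282;Igf2r;535;1772;1704
Egfr;193;Ereg;422;288;153
Egfr;193;Tgfa;261;13;21
Il1r1;180;Il1rn;3515;16;10
Acvr2b;166;Bmp4;1335;66;252
Il1r2;127;Il1rn;3515;16;10
Osm;112;Osmr;1151;1349;131
"),
  gmp = tab("
p;pi;s;si;n;o
Cxcr4;768;Cxcl12;12222;23;798
Egfr;182;Ereg;422;288;153
Il2rg;869;Il7;189;92;255
Itga4;171;Jam2;201;16;26
Itgb1;122;Jam2;201;16;26
Itgb2;969;Jam3;152;42;204
Egfr;182;Tgfa;261;13;21
Itga4;171;Vcam1;692;182;929
Itgb1;122;Vcam1;692;182;929
Nrp1;120;Vegfa;179;1006;169
Nrp1;120;Vegfb;174;191;639
"),
  prob = tab("
p;pi;s;si;n;o
Acvr2a;139;Bmp4;1335;66;252
Acvr2b;178;Bmp4;1335;66;252
Cd28;439;Cd80;462;38;71
Egfr;193;Ereg;422;288;153
Igf2;113;Igf2r;535;1772;1704
Il2rg;3348;Il7;189;92;255
L1cam;596;Ncam1;129;740;545
Osm;143;Osmr;1151;1349;131
Pdgfb;122;Pdgfra;2140;1066;445
Pdgfb;122;Pdgfrb;1829;505;1782
Ccr2;141;Ccl2;239;3362;362
Ccr9;376;Ccl25;123;55;100
Cxcr4;702;Cxcl12;12222;23;798
Egfr;193;Tgfa;261;13;21
Itga4;413;Vcam1;692;182;929
Itgb7;2879;Vcam1;692;182;929
Itgb1;130;Vcam1;692;182;929
Nrp1;333;Vegfa;275;1872;387
Kdr;389;Vegfa;275;1872;387
Itgb1;130;Jam2;201;16;26
Itga4;413;Jam2;201;16;26
Itgb2;4429;Jam3;152;42;204
"),
  preb = tab("
p;pi;s;si;n;o
Cxcr4;1526;Cxcl12;12222;23;798
Egfr;177;Ereg;422;288;153
Il2rg;2147;Il7;189;92;255
Itga4;199;Jam2;201;16;26
Itgb2;1438;Jam3;152;42;204
Osm;101;Osmr;1151;1349;131
Egfr;177;Tgfa;261;13;21
Itga4;199;Vcam1;692;182;929
"),
  matureb = tab("
p;pi;s;si;n;o
Cxcr4;1275;Cxcl12;12222;23;798
Egfr;145;Ereg;422;288;153
Il2rg;2746;Il7;189;92;255
Itga4;1640;Jam2;201;16;26
Itgb1;235;Jam2;201;16;26
Itgb2;1781;Jam3;152;42;204
Lta;540;Ltbr;965;285;519
Tgfb1;718;Odc-rs;197;146;14
Egfr;145;Tgfa;261;13;21
Tgfb1;718;Tgfbr2;171;85;253
Tgfb1;718;Tgfbr3;3653;3429;1152
Lta;540;Tnfrsf1a;1974;959;1143
Lta;540;Tnfrsf1b;108;721;108
Itga4;1640;Vcam1;692;182;929
Itgb1;235;Vcam1;692;182;929
Itgb7;942;Vcam1;692;182;929
")
)

labels <- c(lthsc = "LT-HSC", mpp = "MPP", lmpp = "LMPP", clp = "CLP",
            gmp = "GMP", prob = "proB", preb = "preB", matureb = "matureB")

stopifnot(vapply(tables, nrow, 0L) ==
            c(lthsc = 15, mpp = 14, lmpp = 17, clp = 14, gmp = 11,
              prob = 22, preb = 8, matureb = 16))
stopifnot(all(unlist(lapply(tables, function(t)
  c(t$pop_symbol, t$stroma_symbol))) %in% registry$symbol))

look <- function(sym, field) registry[[field]][match(sym, registry$symbol)]

# -- pair database -----------------------------------------------------------
all_rows <- do.call(rbind, tables)
key <- with(all_rows, paste(pmin(pop_symbol, stroma_symbol),
                            pmax(pop_symbol, stroma_symbol), sep = "~"))
first <- !duplicated(key)
pairs <- data.frame(
  pair_id  = sprintf("P%03d", seq_len(sum(first))),
  gene_a   = look(all_rows$pop_symbol[first], "gene"),
  symbol_a = all_rows$pop_symbol[first],
  role_a   = look(all_rows$pop_symbol[first], "role"),
  gene_b   = look(all_rows$stroma_symbol[first], "gene"),
  symbol_b = all_rows$stroma_symbol[first],
  role_b   = look(all_rows$stroma_symbol[first], "role"),
  source   = "transcribed interaction tables",
  stringsAsFactors = FALSE)
cat("global pair database:", nrow(pairs), "pairs\n")
stopifnot(nrow(pairs) == length(unique(key)))

out <- "inst/extdata"
wtsv <- function(d, path, header_lines = character()) {
  con <- file(path, "w")
  if (length(header_lines)) writeLines(header_lines, con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  close(con)
}
wtsv(pairs, file.path(out, "pairs_tables.tsv"))
wtsv(registry[order(registry$symbol), c("gene", "symbol", "role", "description")],
     file.path(out, "gene_registry.tsv"))

# pro-B table alone as a 22-pair database fixture
kp <- key[rep(names(tables), vapply(tables, nrow, 0L)) == "prob"]
t6 <- tables$prob
prob_pairs <- data.frame(
  pair_id  = sprintf("T6-%02d", seq_len(nrow(t6))),
  gene_a   = look(t6$pop_symbol, "gene"),
  symbol_a = t6$pop_symbol,
  role_a   = look(t6$pop_symbol, "role"),
  gene_b   = look(t6$stroma_symbol, "gene"),
  symbol_b = t6$stroma_symbol,
  role_b   = look(t6$stroma_symbol, "role"),
  source   = "transcribed pro-B interaction table",
  stringsAsFactors = FALSE)
stopifnot(length(unique(kp)) == 22)
wtsv(prob_pairs, file.path(out, "pairs_prob_table.tsv"))

# -- per-table profiles and expected outputs ---------------------------------
profile_tsv <- function(sym, intensity, path) {
  stopifnot(!anyDuplicated(sym))
  d <- data.frame(
    probe_set   = paste0(tolower(sym), "_at"),
    accession   = paste0("FX", look(sym, "gene")),
    description = look(sym, "description"),
    gene        = look(sym, "gene"),
    symbol      = sym,
    intensity_1 = intensity,
    call_1      = "P",
    stringsAsFactors = FALSE)
  wtsv(d[order(d$symbol), ], path)
}

uniq_side <- function(t, sym_col, val_col) {
  u <- unique(t[, c(sym_col, val_col)])
  stopifnot(!anyDuplicated(u[[sym_col]]))   # printed values consistent per table
  u
}

direction_of <- function(pr, sr) {
  ifelse(pr == "receptor" & sr == "ligand", "pop_receptor__stroma_ligand",
  ifelse(pr == "ligand" & sr == "receptor", "pop_ligand__stroma_receptor",
         "adhesion_pair"))
}

for (k in names(tables)) {
  t <- tables[[k]]
  up <- uniq_side(t, "pop_symbol", "pop_intensity")
  profile_tsv(up$pop_symbol, up$pop_intensity,
              file.path(out, "tables", sprintf("pop_%s.tsv", k)))
  for (side in list(c("stroma_intensity", "stroma_op9"),
                    c("NIH3T3", "comp_nih3t3"),
                    c("MC3T3", "comp_mc3t3"))) {
    us <- uniq_side(t, "stroma_symbol", side[1])
    profile_tsv(us$stroma_symbol, us[[side[1]]],
                file.path(out, "tables", sprintf("%s_%s.tsv", side[2], k)))
  }
  exp <- data.frame(
    pop_gene         = look(t$pop_symbol, "gene"),
    pop_symbol       = t$pop_symbol,
    pop_intensity    = t$pop_intensity,
    stroma_gene      = look(t$stroma_symbol, "gene"),
    stroma_symbol    = t$stroma_symbol,
    stroma_intensity = t$stroma_intensity,
    direction        = direction_of(look(t$pop_symbol, "role"),
                                    look(t$stroma_symbol, "role")),
    autocrine        = FALSE,
    NIH3T3           = t$NIH3T3,
    MC3T3            = t$MC3T3,
    stringsAsFactors = FALSE)
  exp <- exp[order(tolower(exp$stroma_symbol), tolower(exp$pop_symbol),
                   exp$direction, method = "radix"), ]
  wtsv(exp, file.path(out, "tables", sprintf("expected_%s.tsv", k)),
       c(sprintf("# population: %s", labels[[k]]), "# stroma: OP9"))
}

# -- sanity: the global pair db yields no row beyond the printed set ---------
for (k in names(tables)) {
  t <- tables[[k]]
  popg <- unique(t$pop_symbol); strg <- unique(t$stroma_symbol)
  emitted <- character()
  for (i in seq_len(nrow(pairs))) for (sw in c(FALSE, TRUE)) {
    a <- if (sw) pairs$symbol_b[i] else pairs$symbol_a[i]
    b <- if (sw) pairs$symbol_a[i] else pairs$symbol_b[i]
    if (a %in% popg && b %in% strg) emitted <- c(emitted, paste(a, b))
  }
  printed <- unique(paste(t$pop_symbol, t$stroma_symbol))
  stopifnot(setequal(emitted, printed), !anyDuplicated(emitted))
}
cat("fixtures written; per-table brute-force check passed\n")
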