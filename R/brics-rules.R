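# Published BRICS retrosynthetic environments and compatible link pairs.
# Alternatives referring to dummy atoms or explicit hydrogens are dropped:
# neither occurs in an intact input molecule.

brics_environments <- c(
  L1  = "[C;D3]([#6,#7,#8])(=O)",
  L3  = "[O;D2]-;!@[#6]",
  L4  = "[C;!D1;!$(C=*)]-;!@[#6]",
  L5  = "[N;!D1;!$(N=*);!$(N-[!#6;!#16]);!$([N;R]@[C;R]=O)]",
  L6  = "[C;D3;!R](=O)-;!@[#6,#7,#8]",
  L7  = "[C;D2,D3]-[#6]",
  L8  = "[C;!R;!D1;!$(C!-*)]",
  L9  = "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
  L10 = "[N;R;$(N(@C(=O))@[C,N,O,S])]",
  L11 = "[S;D2](-;!@[#6])",
  L12 = "[S;D4]([#6])(=O)(=O)",
  L13 = "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
  L14 = "[c;$(c(:[c,n,o,s]):[n,o,s])]",
  L15 = "[C;$(C(-;@C)-;@C)]",
  L16 = "[c;$(c(:c):c)]"
)

# (environment a, environment b, bond symbol); processed in this order, each
# molecular bond is cut at most once (first matching pair wins).
brics_pairs <- list(
  c("L1", "L3", "-"), c("L1", "L5", "-"), c("L1", "L10", "-"),
  c("L3", "L4", "-"), c("L3", "L13", "-"), c("L3", "L14", "-"),
  c("L3", "L15", "-"), c("L3", "L16", "-"),
  c("L4", "L5", "-"), c("L4", "L11", "-"),
  c("L5", "L12", "-"), c("L5", "L14", "-"), c("L5", "L16", "-"),
  c("L5", "L13", "-"), c("L5", "L15", "-"),
  c("L6", "L13", "-"), c("L6", "L14", "-"), c("L6", "L15", "-"),
  c("L6", "L16", "-"),
  c("L7", "L7", "="),
  c("L8", "L9", "-"), c("L8", "L10", "-"), c("L8", "L13", "-"),
  c("L8", "L14", "-"), c("L8", "L15", "-"), c("L8", "L16", "-"),
  c("L9", "L13", "-"), c("L9", "L14", "-"), c("L9", "L15", "-"),
  c("L9", "L16", "-"),
  c("L10", "L13", "-"), c("L10", "L14", "-"), c("L10", "L15", "-"),
  c("L10", "L16", "-"),
  c("L11", "L13", "-"), c("L11", "L14", "-"), c("L11", "L15", "-"),
  c("L11", "L16", "-"),
  c("L13", "L14", "-"), c("L13", "L15", "-"), c("L13", "L16", "-"),
  c("L14", "L14", "-"), c("L14", "L15", "-"), c("L14", "L16", "-"),
  c("L15", "L16", "-"),
  c("L16", "L16", "-")
)

# Joined two-atom SMARTS for one link pair; cuts are never ring bonds.
brics_pair_smarts <- function(pair) {
  bond <- if (pair[[3]] == "=") "=;!@" else "-;!@"
  paste0(
    "[$(", brics_environments[[pair[[1]]]], ")]", bond,
    "[$(", brics_environments[[pair[[2]]]], ")]"
  )
}
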