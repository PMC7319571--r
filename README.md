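# atomcharge

Empirical partial atomic charges for small molecules and biomacromolecules,
in R.

Partial atomic charges are per-atom real numbers that model a molecule's
charge-density distribution. They are not observables, but they drive much
of applied molecular science: electrostatics in docking and molecular
dynamics, QSAR/QSPR descriptors, pKa reasoning, protein surface analysis.
Quantum-chemical charges are accurate but slow; *empirical* schemes get
comparable practical value in milliseconds from tabulated atomic parameters
plus the molecular topology or geometry — fast enough for drug libraries
and whole proteins. This package is for computational chemists,
chemoinformaticians and structural bioinformaticians who need those
charges inside an R workflow.

## What it computes

Ten empirical charge methods behind one front door:

* **Conformationally independent (2D, bond graph only):** PEOE
  (Gasteiger–Marsili partial equalization of orbital electronegativity),
  MGC (Sanderson-style geometric-mean equalization), VEEM
  (valence-electron bond-pair splitting), Del Re (inductive linear
  system).
* **Conformationally dependent (3D, interatomic distances):** EEM, SFKEEM,
  QEq, EQeq and EQeq+C — all instances of electronegativity equalization.
  With a linear atomic energy model, "every atom reaches the same
  effective electronegativity" becomes the constrained linear system

  $$A_i + B_i\,q_i + \sum_{j\neq i} k(i,j,R_{ij})\,q_j \;=\; \bar\chi,
  \qquad \sum_i q_i = Q,$$

  an $(N{+}1)\times(N{+}1)$ solve whose kernel $k$ distinguishes the
  methods (EEM: $\kappa/R_{ij}$; SFKEEM: $2\sqrt{B_iB_j}\,
  \mathrm{sech}(\sigma R_{ij})$; QEq/EQeq: screened Coulomb with the exact
  $k_e/R$ tail). GDAC adds a geometry-damped iterative transfer scheme.

Around the methods: a registry of published parameter sets (JSON, with
citations) with per-molecule applicability checking and automatic
method/set selection; readers for SDF (V2000), MOL2, PDB and mmCIF (plus
zip/tar.gz archives) with validation and covalent-radius bond perception;
writers for PQR, MOL2 and plain text; and cutoff/cover local-subsystem
approximations that scale the equalization methods to macromolecules,
routed automatically at 20 000 / 80 000 atoms.

## Worked example

Charges for propofol (2,6-diisopropylphenol; bundled synthetic conformer),
with automatic method and parameter-set selection:

```r
library(atomcharge)

sdf <- system.file("extdata", "phenols", "propofol_gen3d.sdf",
                   package = "atomcharge")
mol <- read_structures(sdf)$molecules[[1]]
mol
#> <molecule 'propofol': 31 atoms, 31 bonds, Q = +0>

res <- calculate_charges(mol)      # auto: EEM + a drug-like published set
res
#> <charge_result 'propofol': eem/eem-2015-hf-aim, 31 atoms, strategy full>
#>   charges: 0.0360 0.0849 0.0192 -0.0941 -0.0301 -0.0422 -0.0242 -0.1203 ...
#>   sum = +0.000000, chibar = 2.4390
```

The automatic setup picked EEM with the Geidl 2015 HF/AIM parameter set.
`sum = 0` is the total-charge constraint holding exactly; `chibar` is the
equalized molecular electronegativity (in the set's electronegativity
units) that every atom's effective electronegativity reaches at the
solution. `coef(res)` returns the named per-atom charge vector; the
hydroxyl hydrogen carries 0.360 e, the most positive hydrogen in the
molecule — the quantity that tracks phenol acidity (more
electron-withdrawing rings give a more positive phenolic H and a lower
pKa). `plot(res)` draws the per-atom charge profile.

Batch use, method listing and file output mirror a complete workflow:

```r
run_charges(c("ligands.sdf", "receptor.pdb"), "out/",
            formats = c("txt", "pqr"))   # manifest.json + charges.*
list_methods("ligands.sdf")              # methods + sets + applicability
```

or from the shell via the installed script:

```sh
$(Rscript -e 'cat(system.file("exec", "atomcharge", package = "atomcharge"))') \
    charges -i ligands.sdf -o out --format txt,mol2
```

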