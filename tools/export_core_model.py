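"""Export the public BiGG e_coli_core network (as distributed with the COBRA
toolbox / cobrapy 'textbook' model) to two compact TSV fixtures used by the
R package. Run: python tools/export_core_model.py
"""
import cobra, re

m = cobra.io.load_model("textbook")
with open("inst/extdata/e_coli_core_metabolites.tsv","w") as fh:
    fh.write("id\tname\tcompartment\tformula\n")
    for met in sorted(m.metabolites, key=lambda x: x.id):
        fh.write(f"{met.id}\t{met.name}\t{met.compartment}\t{met.formula}\n")

def eqn(r):
    lhs = " + ".join(f"{-c:g} {mm.id}" for mm,c in sorted(r.metabolites.items(), key=lambda t:t[0].id) if c<0)
    rhs = " + ".join(f"{c:g} {mm.id}" for mm,c in sorted(r.metabolites.items(), key=lambda t:t[0].id) if c>0)
    return f"{lhs} <-> {rhs}"

with open("inst/extdata/e_coli_core_reactions.tsv","w") as fh:
    fh.write("id\tname\tlower\tupper\tequation\n")
    for r in sorted(m.reactions, key=lambda x: x.id):
        fh.write(f"{r.id}\t{r.name}\t{r.lower_bound:g}\t{r.upper_bound:g}\t{eqn(r)}\n")
print("wrote", len(m.metabolites), "metabolites,", len(m.reactions), "reactions")
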