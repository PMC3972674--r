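# Model-file grammar (BNGL subset)

A model file is UTF-8 text made of three block kinds. `#` starts a comment;
blank lines are ignored.

```
begin molecule types
  <TypeDecl>*
end molecule types

begin parameters
  <name> <number>
end parameters

begin reaction rules
  <Rule>*
end reaction rules
```

## Molecule types

```
TypeDecl  := Name [ "(" SiteDecl ("," SiteDecl)* ")" ]
SiteDecl  := Name ("~" Label)*
Name      := [A-Za-z_][A-Za-z0-9_]*
```

A site may be declared more than once (generic sites); duplicate
occurrences are interchangeable for matching. `~` labels enumerate the
allowed modification states of a site; the first label is the default
state of newly created particles.

Example: `A(a,a,b~none~mod)` — two interchangeable binding sites `a`, one
modifiable site `b` starting in state `none`.

## Patterns

```
Complex   := Molecule ("." Molecule)*
Molecule  := Name [ "(" SiteP ("," SiteP)* ")" ]
SiteP     := Name [ "~" Label ] [ "!" (Digits | "+" | "?") ]
```

Omitted sites are wildcards: their bond and modification state is not
considered. A mentioned site with no `!` spec must be **unbound**; `!n`
carries a numbered bond shared by exactly two site occurrences of the
complex; `!+` means bound to anything; `!?` leaves the bond state
unspecified. A mentioned site with no `~` label matches any modification
state. Molecules joined by `.` must be connected through shared bond
labels.

## Rules

```
Rule := [ Name ":" ] Complex ("+" Complex)* "->"
        Complex ("+" Complex)* Rate [ "@" Switch ]
Rate := number | parameter name
```

Rules are unidirectional (`<->` is rejected; write two rules). The
molecule multiset is conserved: left and right sides must list the same
molecule types in the same order, mentioning the same sites, and may
differ in at most one bond (formed or broken) plus any number of
modification relabelings. The derived rule kinds are `bind`, `unbind`,
`modify` and `modify-propagate`.

Rates: for bimolecular bind rules the rate is the binding probability per
spatial encounter; for unimolecular rules it is a first-order rate
constant per unit time (fired with probability `1 - exp(-k dt)` per step).

`@tag` gates the rule on a named on/off switch (e.g. the spindle assembly
checkpoint switch `@SAC`).

## Interaction tables

A tab-separated alternative for plain binding networks, one bind rule per
row: columns `protein_a`, `protein_b`, `site_a`, `site_b`, optional
`rate_tag` and `switch_tag`.
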