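<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy model used only for parser tests; not derived from any
     published reconstruction. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="synthetic_toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_aspC" fbc:label="aspC"/>
      <fbc:geneProduct fbc:id="G_tyrB" fbc:label="tyrB"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="uptake" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfProducts>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="AAT" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_aspC"/>
            <fbc:geneProductRef fbc:geneProduct="G_tyrB"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="rev_free" reversible="true" fast="false">
        <listOfReactants>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
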