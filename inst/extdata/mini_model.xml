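<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" level="3" version="1" fbc:required="false" groups:required="false">
  <model id="mini_chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a" name="metabolite a" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_b" name="metabolite b" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_up" value="-10" constant="true"/>
      <parameter id="ub_zero" value="0" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_up" name="a uptake" reversible="true" fast="false" fbc:lowerFluxBound="lb_up" fbc:upperFluxBound="ub_zero">
        <listOfReactants>
          <speciesReference species="M_a" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_conv" name="a to b" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_a" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_b" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProduct fbc:geneProduct="G_gA"/>
            <fbc:and>
              <fbc:geneProduct fbc:geneProduct="G_gB"/>
              <fbc:geneProduct fbc:geneProduct="G_gC"/>
            </fbc:and>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_bio" name="biomass" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_b" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gA" fbc:label="gA"/>
      <fbc:geneProduct fbc:id="G_gB" fbc:label="gB"/>
      <fbc:geneProduct fbc:id="G_gC" fbc:label="gC"/>
    </fbc:listOfGeneProducts>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_bio" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <groups:listOfGroups>
      <groups:group groups:id="grp1" groups:name="Central Metabolism" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_conv"/>
        </groups:listOfMembers>
      </groups:group>
    </groups:listOfGroups>
  </model>
</sbml>
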