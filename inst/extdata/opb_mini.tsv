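id	label	parent	category	domain	iri
opbx:PhysicsDomain	biophysical domain		domain
opbx:FluidDomain	fluid kinetic domain	opbx:PhysicsDomain	domain
opbx:ChemicalDomain	chemical kinetic domain	opbx:PhysicsDomain	domain
opbx:ElectricalDomain	electrical kinetic domain	opbx:PhysicsDomain	domain
opbx:DiffusionDomain	diffusion kinetic domain	opbx:PhysicsDomain	domain
opbx:DynamicalEntity	dynamical entity		entity
opbx:DynamicalProcess	dynamical process		process
opbx:EnergyFlowProcess	energy flow process	opbx:DynamicalProcess	process
opbx:FluidFlowProcess	fluid flow process	opbx:EnergyFlowProcess	process	opbx:FluidDomain
opbx:ChemicalFlowProcess	chemical flow process	opbx:EnergyFlowProcess	process	opbx:ChemicalDomain
opbx:ModulationProcess	modulation process	opbx:DynamicalProcess	process
opbx:DynamicalProperty	dynamical property		property
opbx:DynamicalFlowRate	dynamical flow rate	opbx:DynamicalProperty	property
opbx:ForceProperty	force property	opbx:DynamicalProperty	property
opbx:AmountProperty	amount property	opbx:DynamicalProperty	property
opbx:FluidFlowRate	fluid flow rate	opbx:DynamicalFlowRate	property	opbx:FluidDomain
opbx:ChemicalFlowRate	chemical flow rate	opbx:DynamicalFlowRate	property	opbx:ChemicalDomain
opbx:ChargeFlowRate	charge flow rate	opbx:DynamicalFlowRate	property	opbx:ElectricalDomain
opbx:DiffusionFlowRate	diffusion flow rate	opbx:DynamicalFlowRate	property	opbx:DiffusionDomain
opbx:FluidPressure	fluid pressure	opbx:ForceProperty	property	opbx:FluidDomain
opbx:Voltage	voltage	opbx:ForceProperty	property	opbx:ElectricalDomain
opbx:ChemicalPotential	chemical potential	opbx:ForceProperty	property	opbx:ChemicalDomain
opbx:FluidVolume	fluid volume	opbx:AmountProperty	property	opbx:FluidDomain
opbx:ChemicalAmount	chemical amount	opbx:AmountProperty	property	opbx:ChemicalDomain
opbx:ChemicalConcentration	chemical concentration	opbx:AmountProperty	property	opbx:ChemicalDomain
opbx:ChargeAmount	charge amount	opbx:AmountProperty	property	opbx:ElectricalDomain
opbx:PropertyDependency	physical property dependency		dependency
opbx:ResistiveFlowDependency	resistive flow dependency	opbx:PropertyDependency	dependency
fmax:PortionOfBlood	portion of blood	opbx:DynamicalEntity	entity
fmax:LeftVentricle	left ventricle	opbx:DynamicalEntity	entity
fmax:Aorta	aorta	opbx:DynamicalEntity	entity
fmax:Cytosol	cytosol	opbx:DynamicalEntity	entity
chebix:Glucose	glucose	opbx:DynamicalEntity	entity		http://purl.obolibrary.org/obo/CHEBI_17234
chebix:GlucoseSixPhosphate	glucose 6-phosphate	opbx:DynamicalEntity	entity		http://purl.obolibrary.org/obo/CHEBI_4170
chebix:FructoseSixPhosphate	fructose 6-phosphate	opbx:DynamicalEntity	entity
chebix:FructoseBisphosphate	fructose 1,6-bisphosphate	opbx:DynamicalEntity	entity
chebix:Phosphoenolpyruvate	phosphoenolpyruvate	opbx:DynamicalEntity	entity
chebix:Pyruvate	pyruvate	opbx:DynamicalEntity	entity		http://purl.obolibrary.org/obo/CHEBI_15361
chebix:Hexokinase	hexokinase	opbx:DynamicalEntity	entity
chebix:Citrate	citrate	opbx:DynamicalEntity	entity
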